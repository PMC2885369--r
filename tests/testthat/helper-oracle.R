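# Independent pure-R oracles and small fixture builders.

# brute-force affine-gap local alignment (three-matrix DP); independent of
# the compiled aligner it is used to check
sw_oracle <- function(q, s, match = 1, mismatch = -3,
                      gap_open = 5, gap_extend = 2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_extend,
                     H[i, j - 1] - gap_open - gap_extend)
      FF[i, j] <- max(FF[i - 1, j] - gap_extend,
                      H[i - 1, j] - gap_open - gap_extend)
      sub <- if (qc[i - 1] == sc[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], FF[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# replace the base at 1-based position `at` with a different one
mutate_base <- function(seq, at) {
  old <- substr(seq, at, at)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  paste0(substr(seq, 1, at - 1), new, substr(seq, at + 1, nchar(seq)))
}

# independently coded two-class SAM statistic (per-probe loop, plain
# variance formulas) for cross-checking the vectorized implementation
sam_oracle_d <- function(mat, is_b, s0) {
  apply(mat, 1, function(x) {
    a <- x[!is_b]; b <- x[is_b]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2) *
                 (1 / length(a) + 1 / length(b)))
    (mean(b) - mean(a)) / (sp + s0)
  })
}

# small simulated two-strain gDNA experiment used across tests
small_gdna_sim <- function(n_sets = 40, seed = 1, params = sim_params(),
                           genome_length = max(50000, n_sets * 500),
                           amount = 5) {
  gp <- generate_genome_pair(genome_length, params, seed = seed)
  pr <- design_probe_sets(gp, n_sets = n_sets, seed = seed + 1)
  im <- simulate_intensities(pr, gp, "gdna", amount, params,
                             seed = seed + 2)
  list(gp = gp, probes = pr, im = im, lm = log_transform(im),
       truth = data.frame(probe_id = im$probes$probe_id,
                          sfp_truth = im$probes$sfp_truth))
}
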