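#' Simulate raw probe intensities for a two-strain hybridization
#'
#' Generates a raw intensity matrix (PM and MM rows, one column per
#' strain x replicate) under the log10 signal model of [sim_params()]:
#' a signal level (amount class in gDNA mode; per-gene expression draw in
#' transcript mode), an affinity term proportional to the centred duplex
#' \eqn{\Delta G}, a strain term (probes whose footprint overlaps a
#' planted variant lose a per-probe lognormal SFP effect in strain B), and
#' Gaussian noise. A non-specific cross-hybridization background is then
#' added on the raw scale -- its level rises with the applied amount
#' faster than the specific signal (`crosshyb_amount_slope`), so it both
#' floors weak signals and erodes the deficit of mismatched targets at
#' high amounts -- and the total is soft-capped at the saturation
#' ceiling. MM rows follow the same model minus the MM penalty. Raw
#' intensity is `10^log10`.
#'
#' With `frag_dropout_rate > 0`, random 100-250 bp amplification fragments
#' drop out in strain B and every probe they cover loses
#' `frag_dropout_effect` log10 units regardless of SFP status, planting
#' clustered false positives.
#'
#' @param probes probe table from [design_probe_sets()].
#' @param genome the [generate_genome_pair()] the probes were designed on.
#' @param mode "gdna" or "transcript".
#' @param amount_class for gDNA, one of the configured amount classes
#'   (1, 5, or 40 ug by default); for transcript mode, a tissue label.
#' @param params an [sim_params()] object.
#' @param seed integer seed.
#' @return an object of class `intensity_matrix`: a list with `intensity`
#'   (raw matrix, `2 * nrow(probes)` rows named `<probe_id>:PM|MM`),
#'   `samples` (sample_id, strain, mode, amount_or_tissue, replicate),
#'   and `probes` (the probe table augmented with `delta_g`, planted
#'   `sfp_truth`, and `dropout`).
#' @examples
#' gp <- generate_genome_pair(20000, sim_params(), seed = 1)
#' pr <- design_probe_sets(gp, n_sets = 5, seed = 1)
#' im <- simulate_intensities(pr, gp, "gdna", 5, sim_params(), seed = 2)
#' dim(im$intensity)
#' @export
simulate_intensities <- function(probes, genome,
                                 mode = c("gdna", "transcript"),
                                 amount_class = 5, params = sim_params(),
                                 seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(probes)
  if (mode == "gdna") {
    key <- as.character(amount_class)
    if (!key %in% names(params$amount_effect))
      stop("unknown amount class '", key, "'; configured classes: ",
           paste(names(params$amount_effect), collapse = ", "))
    reps <- params$reps_gdna
  } else {
    if (!is.character(amount_class) || length(amount_class) != 1)
      stop("transcript mode needs a single tissue label")
    reps <- params$reps_rna
  }
  dg <- delta_g(probes$pm_sequence)
  dgc <- dg - mean(dg)
  truth <- probe_truth_from_variants(probes, genome)

  # tissue-specific expression stream: offset the seed by a label hash so
  # different tissues get different (but reproducible) expression profiles
  seed_off <- if (mode == "transcript")
    sum(utf8ToInt(amount_class)) %% 1000L else 0L

  withr::with_seed(as.integer(seed) + seed_off, {
    if (mode == "gdna") {
      level <- rep(params$baseline_log10 + params$amount_effect[[key]], n)
    } else {
      sets <- unique(probes$set_id)
      el <- params$expression_law
      low <- runif(length(sets)) < el$p_low
      expr <- rnorm(length(sets),
                    mean = ifelse(low, el$low_mean, el$high_mean),
                    sd = el$sd)
      level <- setNames(expr, sets)[probes$set_id]
    }

    # per-probe SFP effect: lognormal with the configured mean/SD, scaled
    # by the affinity coupling (strong binders can lose less signal)
    eff <- numeric(n)
    if (any(truth)) {
      m <- params$sfp_effect_mean; s <- params$sfp_effect_sd
      if (s > 0) {
        sdlog <- sqrt(log(1 + (s / m)^2))
        eff[truth] <- rlnorm(sum(truth), log(m) - sdlog^2 / 2, sdlog)
      } else eff[truth] <- m
      if (params$sfp_affinity_coupling != 0)
        eff[truth] <- eff[truth] *
          exp(params$sfp_affinity_coupling * dgc[truth])
    }

    # amplification-polymorphism dropout fragments in strain B
    dropout <- rep(FALSE, n)
    if (params$frag_dropout_rate > 0) {
      glen <- nchar(genome$seq_a)
      fr <- params$frag_len_range
      starts <- ends <- integer(0)
      pos <- 0L
      while (pos < glen) {
        flen <- sample(fr[1]:fr[2], 1L)
        if (runif(1) < params$frag_dropout_rate) {
          starts <- c(starts, pos); ends <- c(ends, pos + flen)
        }
        pos <- pos + flen
      }
      if (length(starts)) {
        pe <- probes$start + nchar(probes$pm_sequence)
        dropout <- vapply(seq_len(n), function(i) {
          any(starts < pe[i] & ends > probes$start[i])
        }, logical(1))
      }
    }

    strains <- c("A", "B")
    cols <- expand.grid(replicate = seq_len(reps), strain = strains,
                        stringsAsFactors = FALSE)[, c("strain", "replicate")]
    sample_id <- sprintf("%s_%s_r%d", cols$strain,
                         gsub("[^A-Za-z0-9]", "", as.character(amount_class)),
                         cols$replicate)
    core <- level + params$affinity_slope * dgc
    # non-specific background level for this condition (raw-scale additive)
    bg <- if (mode == "gdna") {
      params$crosshyb_floor +
        params$crosshyb_amount_slope * params$amount_effect[[key]]
    } else params$crosshyb_floor
    mat <- matrix(NA_real_, nrow = 2L * n, ncol = nrow(cols))
    rownames(mat) <- c(paste0(probes$probe_id, ":PM"),
                       paste0(probes$probe_id, ":MM"))
    colnames(mat) <- sample_id
    for (j in seq_len(nrow(cols))) {
      strain_term <- if (cols$strain[j] == "B")
        -(eff * truth) - params$frag_dropout_effect * dropout else 0
      pm <- core + strain_term + rnorm(n, 0, params$noise_sd)
      mm <- core + strain_term - params$mm_penalty +
        rnorm(n, 0, params$noise_sd)
      y <- c(pm, mm)
      if (is.finite(bg)) y <- y + log1p(10^(bg - y)) / log(10)
      y <- soft_cap(y, params$saturation_ceiling,
                    params$saturation_sharpness)
      mat[, j] <- 10^y
    }
    probes$delta_g <- dg
    probes$sfp_truth <- truth
    probes$dropout <- dropout
    structure(list(intensity = mat,
                   samples = data.frame(sample_id = sample_id,
                                        strain = cols$strain, mode = mode,
                                        amount_or_tissue =
                                          as.character(amount_class),
                                        replicate = cols$replicate,
                                        stringsAsFactors = FALSE),
                   probes = probes, mode = mode, seed = seed),
              class = "intensity_matrix")
  })
}

# smooth soft-minimum of y and ceiling c: -log(exp(-k*y) + exp(-k*c))/k,
# computed stably; exact identity when c is infinite
soft_cap <- function(y, ceiling, sharpness) {
  if (!is.finite(ceiling)) return(y)
  k <- sharpness
  m <- pmin(y, ceiling)
  m - log1p(exp(-k * abs(y - ceiling))) / k
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("Simulated %s intensities (%s): %d probe pairs x %d samples\n",
              x$mode, x$samples$amount_or_tissue[1],
              nrow(x$intensity) / 2, ncol(x$intensity)))
  cat(sprintf("  planted SFP probes: %d / %d (%.1f%%)\n",
              sum(x$probes$sfp_truth), nrow(x$probes),
              100 * mean(x$probes$sfp_truth)))
  invisible(x)
}

#' Log-transform raw intensities
#'
#' Applies `log10(max(raw, floor))` to the raw intensity matrix; no
#' background correction and no normalization is done (plain
#' log-transformed raw PM values give the best SFP detection performance).
#'
#' @param raw an `intensity_matrix` from [simulate_intensities()] (or a
#'   bare numeric matrix).
#' @param floor raw-unit floor before the log (default 1, so a zero
#'   intensity maps to log10 = 0).
#' @return an object of class `log_intensity_matrix` mirroring the input
#'   with a `log10` matrix, or a bare matrix if the input was bare.
#' @examples
#' log_transform(matrix(c(1000, 0), 2, 1))
#' @export
log_transform <- function(raw, floor = 1) {
  tf <- function(m) {
    if (any(m < 0)) stop("negative intensities are not allowed")
    log10(pmax(m, floor))
  }
  if (is.matrix(raw) || is.numeric(raw)) return(tf(raw))
  stopifnot(inherits(raw, "intensity_matrix"))
  out <- raw
  out$log10 <- tf(raw$intensity)
  out$intensity <- NULL
  class(out) <- "log_intensity_matrix"
  out
}

#' @export
print.log_intensity_matrix <- function(x, ...) {
  cat(sprintf("log10 %s intensities: %d probe pairs x %d samples\n",
              x$mode, nrow(x$log10) / 2, ncol(x$log10)))
  invisible(x)
}

#' Extract PM or MM rows from a (log-)intensity object
#'
#' @param x an `intensity_matrix` or `log_intensity_matrix`.
#' @return a numeric matrix with one row per probe, named by probe id.
#' @export
pm_matrix <- function(x) half_matrix(x, "PM")

#' @rdname pm_matrix
#' @export
mm_matrix <- function(x) half_matrix(x, "MM")

half_matrix <- function(x, which) {
  m <- if (inherits(x, "log_intensity_matrix")) x$log10 else x$intensity
  sel <- paste0(x$probes$probe_id, ":", which)
  out <- m[sel, , drop = FALSE]
  rownames(out) <- x$probes$probe_id
  out
}
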