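#' Design probe sets on a genome
#'
#' Places `n_sets` probe sets along `seq_a`, each confined to one
#' `set_span` bp window (mirroring sets concentrated in a ~300-500 bp
#' region near the 3' end of a gene), with `probes_per_set` 25-mer
#' perfect-match probes at distinct starts inside the window. The mismatch
#' probe substitutes the complementary base at the 13th (central) position.
#' Coordinates are 0-based half-open on the plus strand of `seq_a`.
#'
#' @param genome a [generate_genome_pair()] object.
#' @param n_sets number of probe sets.
#' @param probes_per_set probes per set (default 11 pairs).
#' @param set_span width of the window holding one set (default 400 bp).
#' @param seed integer seed.
#' @return a data.frame with columns `probe_id`, `set_id`, `chrom`,
#'   `start`, `strand`, `pm_sequence`, `mm_sequence`.
#' @examples
#' gp <- generate_genome_pair(20000, sim_params(snp_rate = 0), seed = 1)
#' pr <- design_probe_sets(gp, n_sets = 10, seed = 1)
#' nrow(pr)
#' @export
design_probe_sets <- function(genome, n_sets, probes_per_set = 11,
                              set_span = 400, seed = 1) {
  probe_len <- 25L
  if (set_span < probe_len)
    stop("set_span (", set_span, ") is shorter than the probe length (",
         probe_len, ")")
  n_starts <- set_span - probe_len + 1L
  if (n_starts < probes_per_set)
    stop("set_span too small for ", probes_per_set, " distinct probe starts")
  glen <- nchar(genome$seq_a)
  slot <- floor(glen / n_sets)
  if (slot < set_span)
    stop("genome too short for ", n_sets, " sets of span ", set_span)
  withr::with_seed(seed, {
    offs <- floor(runif(n_sets) * (slot - set_span + 1L))
    set_start <- (seq_len(n_sets) - 1L) * slot + offs
    starts <- lapply(seq_len(n_sets), function(i) {
      sort(set_start[i] + sample.int(n_starts, probes_per_set) - 1L)
    })
  })
  start <- as.integer(unlist(starts))
  set_id <- rep(sprintf("s%05d", seq_len(n_sets)), each = probes_per_set)
  probe_id <- sprintf("%s_p%02d", set_id,
                      rep(seq_len(probes_per_set), times = n_sets))
  pm <- substring(genome$seq_a, start + 1L, start + probe_len)
  data.frame(probe_id = probe_id, set_id = set_id, chrom = genome$chrom,
             start = start, strand = "+", pm_sequence = pm,
             mm_sequence = mm_from_pm(pm), stringsAsFactors = FALSE)
}

#' Derive the mismatch probe from a perfect-match probe
#'
#' Substitutes the complementary base at the 13th position (the midpoint of
#' a 25-mer), the standard mismatch-probe construction.
#'
#' @param pm character vector of 25-mer probe sequences.
#' @param at 1-based substitution position (default 13).
#' @return character vector of mismatch sequences.
#' @examples
#' mm_from_pm("AAAAAAAAAAAAGAAAAAAAAAAAA")
#' @export
mm_from_pm <- function(pm, at = 13L) {
  stopifnot(all(nchar(pm) >= at))
  mid <- chartr("ACGT", "TGCA", substr(pm, at, at))
  paste0(substr(pm, 1L, at - 1L), mid, substr(pm, at + 1L, nchar(pm)))
}
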