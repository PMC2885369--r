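#' Classify probes by uniqueness in a reference genome
#'
#' Searches every probe against both strands of genome A and partitions
#' probes into three classes: `unique` (exactly one hit at `min_score`,
#' and that hit is a perfect score-25 full-length match), `multi_hit`
#' (two or more hits), and `no_perfect_match` (no hit, or a single
#' imperfect hit). Only unique probes are usable for SFP detection.
#'
#' @param probes probe table from [design_probe_sets()] (needs `probe_id`
#'   and `pm_sequence`).
#' @param genome_a reference genome sequence (character string) or a
#'   `genome_pair` (its `seq_a` is used).
#' @param min_score minimum hit score (default 18).
#' @return a data.frame (one row per probe): `probe_id`, `class_a`,
#'   `hits_a` (perfect-hit count), `n_hits_a` (all hits at `min_score`),
#'   `best_score_a`.
#' @export
classify_probes <- function(probes, genome_a, min_score = 18) {
  if (inherits(genome_a, "genome_pair")) genome_a <- genome_a$seq_a
  hits <- find_hits_batch(setNames(probes$pm_sequence, probes$probe_id),
                          genome_a, min_score)
  n_hits <- tab_count(hits$probe_id, probes$probe_id)
  perfect <- tab_count(hits$probe_id[hits$score == 25], probes$probe_id)
  best <- rep(0L, nrow(probes))
  if (nrow(hits)) {
    bs <- tapply(hits$score, factor(hits$probe_id,
                                    levels = probes$probe_id), max)
    best <- as.integer(ifelse(is.na(bs), 0L, bs))
  }
  class_a <- ifelse(n_hits >= 2, "multi_hit",
                    ifelse(n_hits == 1 & perfect == 1, "unique",
                           "no_perfect_match"))
  data.frame(probe_id = probes$probe_id, class_a = class_a,
             hits_a = perfect, n_hits_a = n_hits, best_score_a = best,
             stringsAsFactors = FALSE)
}

tab_count <- function(x, levels) {
  as.integer(table(factor(x, levels = levels)))
}

#' Predict SFP truth against the second genome
#'
#' For probes unique in genome A, searches genome B and flags a probe as a
#' sequence-predicted SFP when genome B contains no perfect full-length
#' (score 25) match anywhere. Probes with multiple hits in genome B are
#' retained, not eliminated. Non-unique probes get `sfp_truth = NA`.
#'
#' @param annotation output of [classify_probes()].
#' @param probes the probe table the annotation was computed from.
#' @param genome_b second genome sequence (character string) or a
#'   `genome_pair` (its `seq_b` is used).
#' @param min_score minimum hit score for `best_score_b` (default 18).
#' @return the annotation with `hits_b` (perfect-hit count in B),
#'   `best_score_b`, and logical `sfp_truth` appended.
#' @export
predict_sfp_truth <- function(annotation, probes, genome_b,
                              min_score = 18) {
  if (inherits(genome_b, "genome_pair")) genome_b <- genome_b$seq_b
  stopifnot(identical(annotation$probe_id, probes$probe_id))
  uniq <- annotation$class_a == "unique"
  hits_b <- rep(NA_integer_, nrow(annotation))
  best_b <- rep(NA_integer_, nrow(annotation))
  if (any(uniq)) {
    hits <- find_hits_batch(setNames(probes$pm_sequence[uniq],
                                     probes$probe_id[uniq]),
                            genome_b, min_score)
    hits_b[uniq] <- tab_count(hits$probe_id[hits$score == 25],
                              probes$probe_id[uniq])
    bb <- rep(0L, sum(uniq))
    if (nrow(hits)) {
      bs <- tapply(hits$score, factor(hits$probe_id,
                                      levels = probes$probe_id[uniq]), max)
      bb <- as.integer(ifelse(is.na(bs), 0L, bs))
    }
    best_b[uniq] <- bb
  }
  annotation$hits_b <- hits_b
  annotation$best_score_b <- best_b
  annotation$sfp_truth <- ifelse(uniq, hits_b == 0L, NA)
  annotation
}

#' Select probe sets with enough unique probes for set-based calling
#'
#' Within-set outlier calling needs several probes per set; sets with more
#' than six unique probes (i.e. at least `min_unique = 7`) are retained.
#'
#' @param annotation annotation with `class_a` populated.
#' @param probes probe table (for `set_id` membership).
#' @param min_unique minimum unique probes per retained set (default 7).
#' @return character vector of retained `set_id`s.
#' @export
select_transcript_sets <- function(annotation, probes, min_unique = 7) {
  stopifnot(identical(annotation$probe_id, probes$probe_id))
  uniq_by_set <- tapply(annotation$class_a == "unique", probes$set_id, sum)
  names(uniq_by_set)[uniq_by_set >= min_unique]
}

#' Uniqueness and SFP-truth summary table
#'
#' Counts probes per uniqueness class and sequence-predicted SFPs at probe
#' and probe-set level (a probe set counts as unique/SFP when it contains
#' at least one such probe).
#'
#' @param annotation annotation from [predict_sfp_truth()].
#' @param probes probe table.
#' @return a data.frame with `item`, `probes`, `probe_sets` counts.
#' @export
annotation_summary <- function(annotation, probes) {
  stopifnot(identical(annotation$probe_id, probes$probe_id))
  uniq <- annotation$class_a == "unique"
  sfp <- !is.na(annotation$sfp_truth) & annotation$sfp_truth
  set_of <- probes$set_id
  n_sets_with <- function(flag) length(unique(set_of[flag]))
  data.frame(
    item = c("total", "no_perfect_match", "multi_hit", "unique",
             "sfp_in_unique"),
    probes = c(nrow(annotation),
               sum(annotation$class_a == "no_perfect_match"),
               sum(annotation$class_a == "multi_hit"),
               sum(uniq), sum(sfp)),
    probe_sets = c(length(unique(set_of)), NA, NA,
                   n_sets_with(uniq), n_sets_with(sfp)),
    stringsAsFactors = FALSE
  )
}
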