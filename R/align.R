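#' BLASTN-equivalent local alignment score of a 25-mer probe
#'
#' Scores the best local alignment of a probe against a candidate target
#' window under the probe-search scoring scheme: match +1, mismatch -3,
#' gap of length k costs 5 + 2k (affine). Terminal mismatches and gaps are
#' trimmed by the local alignment, so a complete match scores 25, a single
#' inner mismatch 21 (distal mismatches 24-22), and a single inner base
#' inserted in the target 18.
#'
#' @param probe a 25-mer probe sequence.
#' @param target candidate target window (any length >= 1).
#' @return integer best local alignment score.
#' @examples
#' p <- "ACGTACGTACGTACGTACGTACGTA"
#' score_alignment(p, p)  # 25
#' @export
score_alignment <- function(probe, target) {
  if (nchar(probe) != 25) stop("probe must be a 25-mer")
  if (nchar(target) < 1) stop("empty target")
  sw_align_cpp(probe, target, 1L, -3L, 5L, 2L)[["score"]]
}

#' Find all scoring hits of probes in a genome
#'
#' Exhaustively locates every local alignment of each 25-mer probe with
#' score at least `min_score` on both strands of a genome. Candidate loci
#' are seeded by exact 11-mer matches (every alignment scoring >= 18 under
#' this scheme necessarily contains an exact run of at least 11 bases, so
#' the seeded scan is complete for the default threshold), then scored by
#' the affine-gap local aligner; nearby seed diagonals are merged so each
#' locus is reported once.
#'
#' @param probe a single 25-mer (for [find_hits()]) or a character vector
#'   of 25-mers (for [find_hits_batch()]).
#' @param genome genome sequence as a character string.
#' @param min_score minimum reported score (default 18; scores below 18
#'   are discarded).
#' @return a data.frame of hits: `probe_id` (index or name), `chrom`
#'   (`"seq"`), `start` (0-based, genome forward coordinates), `strand`,
#'   `score`, `aligned_span`.
#' @examples
#' g <- paste(rep("ACGT", 100), collapse = "")
#' find_hits("ACGTACGTACGTACGTACGTACGTA", paste0(g, "TTTTT"), 25)[1, ]
#' @export
find_hits <- function(probe, genome, min_score = 18) {
  if (nchar(probe) != 25) stop("probe must be a 25-mer")
  find_hits_batch(setNames(probe, "probe"), genome, min_score)
}

#' @rdname find_hits
#' @export
find_hits_batch <- function(probe, genome, min_score = 18) {
  if (is.null(genome) || !nzchar(genome)) stop("empty genome")
  if (any(nchar(probe) != 25)) stop("all probes must be 25-mers")
  ids <- names(probe) %||% as.character(seq_along(probe))
  fwd <- scan_strand(probe, genome, min_score)
  rev <- scan_strand(probe, revcomp(genome), min_score)
  glen <- nchar(genome)
  if (nrow(rev)) {
    # map window back to forward coordinates
    rev$start <- glen - (rev$start + rev$aligned_span)
    rev$strand <- "-"
  }
  hits <- rbind(fwd, rev)
  if (nrow(hits) == 0) {
    return(data.frame(probe_id = character(), chrom = character(),
                      start = integer(), strand = character(),
                      score = integer(), aligned_span = integer(),
                      stringsAsFactors = FALSE))
  }
  hits$probe_id <- ids[hits$probe_idx]
  hits$chrom <- "seq"
  hits <- hits[order(match(hits$probe_id, ids), hits$start), ]
  rownames(hits) <- NULL
  hits[, c("probe_id", "chrom", "start", "strand", "score", "aligned_span")]
}

SEED_LEN <- 11L

# one-strand seeded scan; returns probe_idx, start (0-based on this
# strand), strand "+", score, aligned_span
scan_strand <- function(probe, genome, min_score) {
  n_off <- 25L - SEED_LEN + 1L
  seeds <- unlist(lapply(probe, function(p)
    substring(p, 1:n_off, SEED_LEN:25)), use.names = FALSE)
  probe_idx <- rep(seq_along(probe), each = n_off)
  offset <- rep(0:(n_off - 1L), times = length(probe))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(genome))
  st <- Biostrings::startIndex(mi)
  nh <- lengths(st)
  hit_pat <- rep(seq_along(st), nh)
  if (length(hit_pat) == 0) {
    return(data.frame(probe_idx = integer(), start = integer(),
                      strand = character(), score = integer(),
                      aligned_span = integer(), stringsAsFactors = FALSE))
  }
  cand <- data.frame(
    probe_idx = probe_idx[hit_pat],
    # implied probe start on the genome, 1-based
    pstart = unlist(st) - offset[hit_pat]
  )
  cand <- unique(cand)
  cand <- cand[order(cand$probe_idx, cand$pstart), ]
  # merge candidate diagonals within 5 bp of each other (same locus, the
  # shift coming from an indel or a second seed)
  new_locus <- c(TRUE, diff(cand$pstart) > 5L |
                   diff(cand$probe_idx) != 0L)
  locus <- cumsum(new_locus)
  first <- !duplicated(locus)
  loc <- cand[first, ]
  glen <- nchar(genome)
  pad <- 4L
  ws <- pmax(1L, loc$pstart - pad)
  we <- pmin(glen, loc$pstart + 24L + pad)
  windows <- substring(genome, ws, we)
  aln <- sw_align_batch_cpp(unname(probe[loc$probe_idx]), windows,
                            1L, -3L, 5L, 2L)
  keep <- which(aln[, "score"] >= min_score)
  aln <- aln[keep, , drop = FALSE]
  data.frame(probe_idx = loc$probe_idx[keep],
             start = ws[keep] + aln[, "sstart"] - 2L,  # 0-based
             strand = rep("+", length(keep)),
             score = aln[, "score"],
             aligned_span = aln[, "send"] - aln[, "sstart"] + 1L,
             stringsAsFactors = FALSE)
}
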