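#' Generate a synthetic genome pair with planted variants
#'
#' Draws a random genome `seq_a` over A/C/G/T and derives `seq_b` by
#' planting SNPs, short indels, and optional tandem duplications at the
#' configured per-bp rates. Per-type variant counts are binomial at those
#' rates; variants are non-overlapping (later drawn variants whose
#' footprint collides with an earlier one are dropped) so `seq_b` is
#' reconstructed exactly by applying the variant list in coordinate order.
#'
#' @param length genome length in bp (>= 1000).
#' @param params an [sim_params()] object; `snp_rate`, `indel_rate`, and
#'   `duplication_rate` are used here.
#' @param seed integer seed; identical inputs and seed give a
#'   byte-identical result.
#' @return an object of class `genome_pair`: a list with `seq_a`, `seq_b`
#'   (character strings), `chrom` (sequence name), and `variants`, a
#'   data.frame with 0-based `pos` in `seq_a` coordinates, `type` in
#'   snp/insertion/deletion/duplication, and `detail` ("A>G" for SNPs, the
#'   inserted/deleted bases for indels, the span length for duplications).
#' @examples
#' gp <- generate_genome_pair(5000, sim_params(snp_rate = 0.002), seed = 1)
#' nrow(gp$variants)
#' @export
generate_genome_pair <- function(length, params = sim_params(), seed = 1) {
  if (length < 1000) stop("genome length must be at least 1000 bp")
  withr::with_seed(seed, {
    seq_a <- paste(sample(BASES, length, replace = TRUE), collapse = "")
    a <- strsplit(seq_a, "")[[1]]

    # SNPs: per-bp Bernoulli draws
    snp_pos <- which(runif(length) < params$snp_rate) - 1L
    snp <- if (base::length(snp_pos)) {
      ref <- a[snp_pos + 1L]
      alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L),
                    character(1), USE.NAMES = FALSE)
      data.frame(pos = snp_pos, type = "snp",
                 detail = paste0(ref, ">", alt),
                 stringsAsFactors = FALSE)
    } else empty_variants()

    # short indels, length 1-3, half insertions / half deletions
    ind_pos <- which(runif(length) < params$indel_rate) - 1L
    ind_pos <- ind_pos[ind_pos >= 4L & ind_pos < length - 4L]
    ind <- if (base::length(ind_pos)) {
      is_ins <- runif(base::length(ind_pos)) < 0.5
      len <- sample(1:3, base::length(ind_pos), replace = TRUE)
      detail <- character(base::length(ind_pos))
      for (i in seq_along(ind_pos)) {
        detail[i] <- if (is_ins[i]) {
          paste(sample(BASES, len[i], replace = TRUE), collapse = "")
        } else {
          substr(seq_a, ind_pos[i] + 1L, ind_pos[i] + len[i])
        }
      }
      data.frame(pos = ind_pos,
                 type = ifelse(is_ins, "insertion", "deletion"),
                 detail = detail, stringsAsFactors = FALSE)
    } else empty_variants()

    # tandem duplications of 300-500 bp spans, one chance per 5 kb segment
    n_seg <- max(0L, floor(length / 5000))
    dup <- empty_variants()
    if (n_seg > 0 && params$duplication_rate > 0) {
      hit <- which(runif(n_seg) < params$duplication_rate)
      if (base::length(hit)) {
        spans <- sample(300:500, base::length(hit), replace = TRUE)
        pos <- (hit - 1L) * 5000L +
          floor(runif(base::length(hit)) * pmax(1, 5000 - spans))
        keep <- pos + spans < length
        dup <- data.frame(pos = as.integer(pos[keep]), type = "duplication",
                          detail = as.character(spans[keep]),
                          stringsAsFactors = FALSE)
      }
    }

    variants <- rbind(snp, ind, dup)
    variants <- variants[order(variants$pos), , drop = FALSE]
    variants <- drop_overlapping(variants)
    rownames(variants) <- NULL

    structure(list(seq_a = seq_a,
                   seq_b = apply_variants(seq_a, variants),
                   chrom = "chr1", variants = variants),
              class = "genome_pair")
  })
}

empty_variants <- function() {
  data.frame(pos = integer(), type = character(), detail = character(),
             stringsAsFactors = FALSE)
}

variant_span <- function(variants) {
  len <- rep(1L, nrow(variants))
  del <- variants$type == "deletion"
  len[del] <- nchar(variants$detail[del])
  dup <- variants$type == "duplication"
  len[dup] <- as.integer(variants$detail[dup])
  len
}

drop_overlapping <- function(variants) {
  if (nrow(variants) < 2) return(variants)
  len <- variant_span(variants)
  keep <- logical(nrow(variants))
  last_end <- -1L
  for (i in seq_len(nrow(variants))) {
    if (variants$pos[i] > last_end) {
      keep[i] <- TRUE
      last_end <- variants$pos[i] + len[i] - 1L
    }
  }
  variants[keep, , drop = FALSE]
}

#' Apply a variant list to a sequence
#'
#' Reconstructs the second genome from the first plus its variant table
#' (the derivability invariant of [generate_genome_pair()]).
#'
#' @param seq_a reference sequence (character string).
#' @param variants data.frame with `pos` (0-based), `type`, `detail` as
#'   produced by [generate_genome_pair()]; must be coordinate-sorted and
#'   non-overlapping.
#' @return the derived sequence as a character string.
#' @export
apply_variants <- function(seq_a, variants) {
  if (nrow(variants) == 0) return(seq_a)
  variants <- variants[order(variants$pos), , drop = FALSE]
  pieces <- character(0)
  cur <- 1L  # 1-based cursor in seq_a
  for (i in seq_len(nrow(variants))) {
    p1 <- variants$pos[i] + 1L
    type <- variants$type[i]
    detail <- variants$detail[i]
    if (type == "snp") {
      pieces <- c(pieces, substr(seq_a, cur, p1 - 1L),
                  sub(".*>", "", detail))
      cur <- p1 + 1L
    } else if (type == "insertion") {
      pieces <- c(pieces, substr(seq_a, cur, p1 - 1L), detail)
      cur <- p1
    } else if (type == "deletion") {
      pieces <- c(pieces, substr(seq_a, cur, p1 - 1L))
      cur <- p1 + nchar(detail)
    } else if (type == "duplication") {
      l <- as.integer(detail)
      pieces <- c(pieces, substr(seq_a, cur, p1 + l - 1L),
                  substr(seq_a, p1, p1 + l - 1L))
      cur <- p1 + l
    } else stop("unknown variant type: ", type)
  }
  pieces <- c(pieces, substr(seq_a, cur, nchar(seq_a)))
  paste(pieces, collapse = "")
}

#' @export
print.genome_pair <- function(x, ...) {
  tab <- table(factor(x$variants$type,
                      levels = c("snp", "insertion", "deletion",
                                 "duplication")))
  cat(sprintf("Synthetic genome pair (%s): %d bp vs %d bp\n",
              x$chrom, nchar(x$seq_a), nchar(x$seq_b)))
  cat(sprintf("  planted variants: %d SNPs, %d insertions, %d deletions, %d duplications\n",
              tab["snp"], tab["insertion"], tab["deletion"],
              tab["duplication"]))
  invisible(x)
}

#' Planted SFP truth from the variant list
#'
#' TRUE for probes whose footprint is disrupted by a planted SNP, insertion,
#' or deletion (a substitution or deletion overlapping the 25-bp footprint,
#' or an insertion strictly inside it). Duplications do not disrupt: the
#' perfect target is still present in the second genome. This is the
#' generator-side ground truth; on synthetic data it coincides with the
#' alignment-based truth of [predict_sfp_truth()].
#'
#' @param probes probe table from [design_probe_sets()].
#' @param genome the [generate_genome_pair()] the probes come from.
#' @return logical vector, one element per probe.
#' @export
probe_overlap_truth <- function(probes, genome) {
  probe_truth_from_variants(probes, genome)
}

probe_truth_from_variants <- function(probes, genome) {
  v <- genome$variants
  v <- v[v$type != "duplication", , drop = FALSE]
  if (nrow(v) == 0) return(rep(FALSE, nrow(probes)))
  len <- variant_span(v)
  plen <- nchar(probes$pm_sequence)
  vapply(seq_len(nrow(probes)), function(i) {
    s <- probes$start[i]; e <- s + plen[i]  # [s, e) 0-based half-open
    hit <- (v$type %in% c("snp", "deletion") & v$pos < e & v$pos + len >= s + 1L) |
      (v$type == "insertion" & v$pos > s & v$pos < e)
    any(hit)
  }, logical(1))
}
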