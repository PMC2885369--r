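# Per-probe two-group test and set-based robust outlier calling.

# vectorized two-group t/F test per row; one-sided lower p is the
# probability of a more extreme strain-B deficit
row_two_group <- function(matA, matB) {
  nA <- ncol(matA); nB <- ncol(matB)
  if (nA < 2 || nB < 2)
    stop("variance-based tests need at least 2 replicates per group")
  mA <- rowMeans(matA); mB <- rowMeans(matB)
  ssA <- rowSums((matA - mA)^2); ssB <- rowSums((matB - mB)^2)
  df <- nA + nB - 2
  sp2 <- (ssA + ssB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  diff <- mB - mA
  t <- diff / se
  degenerate <- se == 0
  # zero within-group variance: identical groups are uninformative (p = 1);
  # a nonzero difference with zero variance is an exact separation (p = 0)
  t[degenerate] <- sign(diff[degenerate]) * Inf
  t[degenerate & diff == 0] <- 0
  p_lower <- pt(t, df)
  p_two <- pf(t^2, 1, df, lower.tail = FALSE)
  p_lower[degenerate & diff == 0] <- 1
  p_two[degenerate & diff == 0] <- 1
  list(t = t, F = t^2, df = df, p_lower = p_lower, p_two = p_two,
       diff = diff, degenerate = degenerate)
}

#' Call SFPs by per-probe ANOVA
#'
#' Per-probe two-group comparison of log10 PM intensities between strains.
#' The two-group one-way ANOVA F statistic equals the squared pooled-
#' variance t statistic; with the default one-sided direction (strain-B
#' intensity deficit) the one-sided t tail probability is used, so the
#' null false-call fraction at `alpha` is `alpha`.
#'
#' @inheritParams sam_statistic
#' @param alpha significance level; probes with p < alpha are called.
#' @param sided `"lower"` (default) or `"two"`.
#' @return an `sfp_calls` data.frame with `statistic` (the p-value used
#'   for thresholding), `t`, `F`, `called`, `direction`, `degenerate`.
#' @export
anova_call <- function(x, alpha, strain = NULL,
                       sided = c("lower", "two")) {
  sided <- match.arg(sided)
  g <- get_pm_strain(x, strain)
  is_b <- g$strain == "B"
  res <- row_two_group(g$mat[, !is_b, drop = FALSE],
                       g$mat[, is_b, drop = FALSE])
  p <- if (sided == "lower") res$p_lower else res$p_two
  called <- p < alpha
  direction <- ifelse(called, ifelse(res$diff < 0, "loss", "gain"),
                      NA_character_)
  make_callset(data.frame(probe_id = g$probes$probe_id, statistic = p,
                          t = res$t, F = res$F, called = called,
                          direction = direction,
                          degenerate = res$degenerate,
                          stringsAsFactors = FALSE),
               caller = "anova", threshold = alpha,
               extra = list(sided = sided))
}

#' Randomly group probes into pseudo-sets
#'
#' gDNA hybridization has no transcript structure, so probes are randomly
#' grouped into pseudo-sets of `group_size` (500 by default) before
#' set-based outlier calling. A remainder of at least 50 probes forms its
#' own group; a smaller remainder is merged into the last full group.
#'
#' @param probe_ids character vector of probe ids.
#' @param group_size probes per pseudo-set (default 500).
#' @param seed integer seed; the partition is deterministic given it.
#' @return character vector of group labels aligned with `probe_ids`.
#' @export
group_random <- function(probe_ids, group_size = 500, seed = 1) {
  n <- length(probe_ids)
  if (n < group_size) {
    warning("fewer probes than group_size; using a single group")
    return(rep("g001", n))
  }
  n_full <- n %/% group_size
  rem <- n %% group_size
  idx <- rep(seq_len(n_full), each = group_size)
  if (rem > 0) {
    idx <- c(idx, rep(if (rem >= 50) n_full + 1L else n_full, rem))
  }
  perm <- withr::with_seed(seed, sample.int(n))
  out <- character(n)
  out[perm] <- sprintf("g%03d", idx)
  out
}

#' Call SFPs as robust within-set outliers
#'
#' Within each probe set (transcript mode) or random pseudo-set (gDNA
#' mode), the per-probe between-strain difference of mean log10 PM
#' intensity, \eqn{d_i = \bar{x}_{B,i} - \bar{x}_{A,i}}, is standardized
#' by the set's robust center (median) and scale (MAD x 1.4826), and a
#' probe is called when the one-sided lower normal tail probability of
#' its z-score is below `alpha`. Sets with zero robust scale are skipped
#' with a warning.
#'
#' @inheritParams sam_statistic
#' @param alpha significance level (the operating grid spans 1e-6 down
#'   to 1e-18).
#' @param sets set label per probe; defaults to the probe table's
#'   `set_id` for a `log_intensity_matrix` (use [group_random()] output
#'   for gDNA mode).
#' @param sided `"lower"` (default) or `"two"`.
#' @return an `sfp_calls` data.frame with `statistic` (the tail
#'   p-value), `d`, `z`, `set_id`, `called`, `direction`.
#' @export
snep_call <- function(x, alpha, sets = NULL, strain = NULL,
                      sided = c("lower", "two")) {
  sided <- match.arg(sided)
  g <- get_pm_strain(x, strain)
  if (is.null(sets)) {
    if (is.null(g$probes$set_id))
      stop("sets must be supplied when x carries no set membership")
    sets <- g$probes$set_id
  }
  stopifnot(length(sets) == nrow(g$mat))
  is_b <- g$strain == "B"
  d <- rowMeans(g$mat[, is_b, drop = FALSE]) -
    rowMeans(g$mat[, !is_b, drop = FALSE])
  z <- rep(NA_real_, length(d))
  skipped <- character(0)
  for (s in unique(sets)) {
    ix <- which(sets == s)
    m <- median(d[ix]); sc <- mad(d[ix])
    if (sc == 0) { skipped <- c(skipped, s); next }
    z[ix] <- (d[ix] - m) / sc
  }
  if (length(skipped))
    warning("robust scale is zero; skipped set(s): ",
            paste(skipped, collapse = ", "))
  p <- if (sided == "lower") pnorm(z) else 2 * pnorm(-abs(z))
  called <- !is.na(p) & p < alpha
  direction <- ifelse(called, ifelse(z < 0, "loss", "gain"),
                      NA_character_)
  make_callset(data.frame(probe_id = g$probes$probe_id, statistic = p,
                          d = d, z = z, set_id = sets, called = called,
                          direction = direction, stringsAsFactors = FALSE),
               caller = "snep", threshold = alpha,
               extra = list(sided = sided))
}

#' Filter probe sets by expression level
#'
#' Keeps sets whose median log10 PM intensity exceeds the cutoff in both
#' strains. SFPs are only detectable by transcript hybridization when the
#' gene is expressed; the default cutoff of 2.5 log10 units marks the
#' level above which most PM/MM pairs separate significantly.
#'
#' @param x a `log_intensity_matrix` from transcript-mode simulation.
#' @param cutoff median log10 intensity required in each strain
#'   (default 2.5).
#' @param sets set label per probe (defaults to the probe table).
#' @inheritParams sam_statistic
#' @return character vector of retained set ids.
#' @export
expression_filter <- function(x, cutoff = 2.5, sets = NULL,
                              strain = NULL) {
  g <- get_pm_strain(x, strain)
  if (is.null(sets)) sets <- g$probes$set_id
  keep <- vapply(unique(sets), function(s) {
    ix <- which(sets == s)
    all(vapply(c("A", "B"), function(st) {
      median(g$mat[ix, g$strain == st, drop = FALSE]) > cutoff
    }, logical(1)))
  }, logical(1))
  unique(sets)[keep]
}

#' Per-probe PM vs MM replicate comparison
#'
#' Two-group test between the PM and MM replicate log10 intensities of
#' each probe pair (two-sided F, equivalent to the squared t), used to
#' find the expression level above which PM and MM separate.
#'
#' @param x a `log_intensity_matrix`.
#' @param strain restrict to one strain's replicates (default "A"; `NULL`
#'   uses all samples).
#' @return a data.frame with `probe_id`, `t`, `F`, `p`, and `pm_mean`
#'   (mean PM log10 intensity over the used replicates).
#' @export
pm_mm_pair_test <- function(x, strain = "A") {
  stopifnot(inherits(x, "log_intensity_matrix"))
  cols <- if (is.null(strain)) seq_len(ncol(x$log10))
  else which(x$samples$strain == strain)
  if (length(cols) < 2) stop("need at least 2 replicates")
  pm <- pm_matrix(x)[, cols, drop = FALSE]
  mm <- mm_matrix(x)[, cols, drop = FALSE]
  res <- row_two_group(pm, mm)
  data.frame(probe_id = x$probes$probe_id, t = res$t, F = res$F,
             p = res$p_two, pm_mean = rowMeans(pm),
             stringsAsFactors = FALSE)
}
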