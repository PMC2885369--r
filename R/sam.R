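# Two-class unpaired SAM: relative difference d_i = r_i / (s_i + s0) with
# permutation-based expected order statistics and a delta cutoff.

# accepts a log_intensity_matrix (PM rows used) or a bare probes x samples
# matrix plus an explicit strain vector
get_pm_strain <- function(x, strain = NULL) {
  if (inherits(x, "log_intensity_matrix")) {
    list(mat = pm_matrix(x), strain = x$samples$strain,
         probes = x$probes)
  } else {
    stopifnot(is.matrix(x), !is.null(strain), length(strain) == ncol(x))
    list(mat = x, strain = as.character(strain),
         probes = data.frame(probe_id = rownames(x) %||%
                               as.character(seq_len(nrow(x))),
                             stringsAsFactors = FALSE))
  }
}

two_class_stats <- function(mat, is_b) {
  nA <- sum(!is_b); nB <- sum(is_b)
  if (nA < 1 || nB < 1) stop("both strains need at least one replicate")
  mA <- rowMeans(mat[, !is_b, drop = FALSE])
  mB <- rowMeans(mat[, is_b, drop = FALSE])
  ssA <- rowSums((mat[, !is_b, drop = FALSE] - mA)^2)
  ssB <- rowSums((mat[, is_b, drop = FALSE] - mB)^2)
  df <- nA + nB - 2
  s <- if (df > 0) sqrt((1 / nA + 1 / nB) * (ssA + ssB) / df)
  else rep(NA_real_, nrow(mat))
  list(r = mB - mA, s = s, nA = nA, nB = nB, df = df,
       mA = mA, mB = mB)
}

#' SAM relative-difference statistic
#'
#' Computes the two-class unpaired SAM statistic per probe,
#' \eqn{d_i = (\bar{x}_{B,i} - \bar{x}_{A,i}) / (s_i + s_0)}, where
#' \eqn{s_i} is the pooled standard error of the group difference and
#' \eqn{s_0} the variance-stabilizing fudge factor.
#'
#' @param x a `log_intensity_matrix` (PM rows are used) or a bare probes x
#'   samples matrix of log10 intensities.
#' @param s0 fudge factor; if `NULL`, chosen by [choose_s0()].
#' @param strain strain label per sample ("A"/"B"); taken from the sample
#'   metadata when `x` is a `log_intensity_matrix`.
#' @return a data.frame with `probe_id`, `r` (mean difference B - A), `s`
#'   (standard error), `d`, plus the used `s0` as an attribute.
#' @export
sam_statistic <- function(x, s0 = NULL, strain = NULL) {
  g <- get_pm_strain(x, strain)
  st <- two_class_stats(g$mat, g$strain == "B")
  if (st$df < 1)
    stop("SAM needs at least two replicates in total beyond the group count")
  if (is.null(s0)) s0 <- choose_s0(st$r, st$s)
  out <- data.frame(probe_id = g$probes$probe_id, r = st$r, s = st$s,
                    d = st$r / (st$s + s0), stringsAsFactors = FALSE)
  attr(out, "s0") <- s0
  out
}

#' Choose the SAM fudge factor
#'
#' Standard recipe: candidate values are the 0, 5, ..., 100 percentiles of
#' the per-probe standard errors `s`; for each candidate the coefficient
#' of variation of the median absolute deviation of `d` across 100
#' `s`-quantile windows is computed, and the candidate minimizing it wins.
#' Deterministic given the input.
#'
#' @param r per-probe mean differences.
#' @param s per-probe standard errors.
#' @param degenerate_fraction fraction of the common value returned when
#'   all `s` are (numerically) equal.
#' @return the chosen `s0`.
#' @export
choose_s0 <- function(r, s, degenerate_fraction = 0.05) {
  stopifnot(length(r) == length(s), length(s) >= 2)
  if (length(s) < 100)
    warning("choose_s0 is intended for >= 100 probes")
  if (diff(range(s)) < .Machine$double.eps * max(abs(s), 1)) {
    warning("all standard errors are equal; returning the configured fraction")
    return(s[1] * degenerate_fraction)
  }
  cands <- unname(quantile(s, seq(0, 1, by = 0.05)))
  br <- unique(quantile(s, seq(0, 1, length.out = 101)))
  grp <- cut(s, br, include.lowest = TRUE)
  cv <- vapply(cands, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, grp, stats::mad)
    v <- v[is.finite(v)]
    stats::sd(v) / mean(v)
  }, numeric(1))
  cands[which.min(cv)]
}

# enumerate or sample distinct strain-label permutations; each row gives
# the column indices assigned to pseudo-strain B
sam_permutations <- function(strain, n_perm, seed, balanced = TRUE) {
  is_b <- strain == "B"
  n <- length(strain); nB <- sum(is_b)
  all_b <- utils::combn(n, nB)
  if (balanced && sum(!is_b) == nB && nB %% 2 == 0) {
    from_b <- apply(all_b, 2, function(ix) sum(ix %in% which(is_b)))
    all_b <- all_b[, from_b == nB / 2, drop = FALSE]
  }
  if (ncol(all_b) < 2) stop("fewer than 2 distinct permutations available")
  if (ncol(all_b) > n_perm) {
    keep <- withr::with_seed(seed, sample(ncol(all_b), n_perm))
    all_b <- all_b[, keep, drop = FALSE]
  }
  all_b
}

#' Fit the SAM permutation null for a two-strain comparison
#'
#' Computes the observed SAM statistics and the expected order statistics
#' \eqn{\bar{d}_{(i)}} from strain-label permutations (balanced
#' permutations when the two groups have equal, even size; capped at
#' `n_perm` with a fixed seed). [sam_call()] thresholds this fit at a
#' given delta, so a single fit serves a whole ROC curve.
#'
#' @inheritParams sam_statistic
#' @param n_perm maximum number of permutations (default 1000).
#' @param seed seed used when permutations are subsampled.
#' @param balanced use only balanced permutations when possible.
#' @return an object of class `sam_fit`: list with `stat` (the
#'   [sam_statistic()] table), `expected` (per-probe expected statistic,
#'   aligned to rank), and bookkeeping.
#' @export
sam_fit <- function(x, n_perm = 1000, seed = 1, s0 = NULL, strain = NULL,
                    balanced = TRUE) {
  g <- get_pm_strain(x, strain)
  stat <- sam_statistic(g$mat, s0 = s0, strain = g$strain)
  stat$probe_id <- g$probes$probe_id
  s0 <- attr(stat, "s0")
  perms <- sam_permutations(g$strain, n_perm, seed, balanced)
  dbar <- rep(0, nrow(stat))
  for (k in seq_len(ncol(perms))) {
    is_b <- seq_along(g$strain) %in% perms[, k]
    st <- two_class_stats(g$mat, is_b)
    dbar <- dbar + sort(st$r / (st$s + s0))
  }
  dbar <- dbar / ncol(perms)
  structure(list(stat = stat, expected_sorted = dbar, s0 = s0,
                 n_perm = ncol(perms)),
            class = "sam_fit")
}

#' Call SFPs by SAM at a given delta
#'
#' Probes are ranked by their SAM statistic; on the loss side (strain-B
#' intensity deficit) the cutoff is the largest ranked statistic whose
#' deviation from its permutation expectation reaches `delta`, and every
#' probe at or below the cutoff is called. Calls nest: a stricter delta
#' calls a subset.
#'
#' @param x a `log_intensity_matrix`, bare matrix (with `strain`), or a
#'   precomputed [sam_fit()].
#' @param delta SAM threshold on the deviation from the expected order
#'   statistic (e.g. the 0.378 operating point for 5 ug gDNA data).
#' @param sided `"lower"` (default; SFPs lose intensity in strain B) or
#'   `"two"`.
#' @inheritParams sam_fit
#' @return an `sfp_calls` data.frame: `probe_id`, `statistic` (d),
#'   `expected`, `called`, `direction`; caller metadata in attributes.
#' @export
sam_call <- function(x, delta, n_perm = 1000, seed = 1, s0 = NULL,
                     strain = NULL, sided = c("lower", "two"),
                     balanced = TRUE) {
  sided <- match.arg(sided)
  fit <- if (inherits(x, "sam_fit")) x
  else sam_fit(x, n_perm = n_perm, seed = seed, s0 = s0, strain = strain,
               balanced = balanced)
  d <- fit$stat$d
  ord <- order(d)
  diffs <- d[ord] - fit$expected_sorted
  called <- rep(FALSE, length(d))
  direction <- rep(NA_character_, length(d))
  low <- which(diffs <= -delta)
  if (length(low)) {
    cut_low <- max(d[ord][low])
    called[d <= cut_low] <- TRUE
    direction[d <= cut_low] <- "loss"
  }
  if (sided == "two") {
    up <- which(diffs >= delta)
    if (length(up)) {
      cut_up <- min(d[ord][up])
      called[d >= cut_up] <- TRUE
      direction[d >= cut_up] <- "gain"
    }
  }
  expected <- numeric(length(d))
  expected[ord] <- fit$expected_sorted
  make_callset(data.frame(probe_id = fit$stat$probe_id, statistic = d,
                          expected = expected, called = called,
                          direction = direction, stringsAsFactors = FALSE),
               caller = "sam", threshold = delta,
               extra = list(s0 = fit$s0, n_perm = fit$n_perm))
}

make_callset <- function(df, caller, threshold, extra = list()) {
  attr(df, "caller") <- caller
  attr(df, "threshold") <- threshold
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("sfp_calls", "data.frame")
  df
}

#' @export
`[.sfp_calls` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (nm in c("caller", "threshold", "s0", "n_perm", "sided"))
      attr(out, nm) <- attr(x, nm)
    class(out) <- class(x)
  }
  out
}

#' @export
print.sfp_calls <- function(x, ...) {
  cat(sprintf("SFP calls by %s at threshold %.4g: %d / %d probes called\n",
              attr(x, "caller"), attr(x, "threshold"), sum(x$called),
              nrow(x)))
  invisible(x)
}
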