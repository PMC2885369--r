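#' Score a call set against sequence-predicted truth
#'
#' Computes the confusion counts and the two headline ratios:
#' sensitivity = correctly called SFPs / expected SFPs, and the
#' false-call rate fpr = falsely called SFPs / all called SFPs (a
#' false-discovery proportion, not 1 - specificity; the conventional
#' 1 - specificity is also reported as `fpr_conventional`). With zero
#' calls the fpr is 0 by convention.
#'
#' @param calls an `sfp_calls` data.frame (or any data.frame with
#'   `probe_id` and logical `called`).
#' @param truth a data.frame with `probe_id` and logical `sfp_truth`
#'   covering the same probe universe (e.g. from [predict_sfp_truth()] or
#'   the planted truth of [simulate_intensities()]).
#' @return an object of class `sfp_eval`: list with `n_expected_sfp`,
#'   `n_called`, `n_true`, `n_false`, `sensitivity`, `fpr`,
#'   `fpr_conventional`.
#' @examples
#' calls <- data.frame(probe_id = c("a", "b"), called = c(TRUE, FALSE))
#' truth <- data.frame(probe_id = c("a", "b"), sfp_truth = c(TRUE, TRUE))
#' evaluate_calls(calls, truth)$sensitivity
#' @export
evaluate_calls <- function(calls, truth) {
  stopifnot(all(c("probe_id", "called") %in% names(calls)),
            all(c("probe_id", "sfp_truth") %in% names(truth)))
  if (!setequal(calls$probe_id, truth$probe_id) ||
      anyDuplicated(calls$probe_id) || anyDuplicated(truth$probe_id))
    stop("calls and truth must cover the same probe universe")
  tr <- truth$sfp_truth[match(calls$probe_id, truth$probe_id)]
  if (anyNA(tr) || anyNA(calls$called))
    stop("calls and truth must be complete (no NA) over the universe")
  n_called <- sum(calls$called)
  n_true <- sum(calls$called & tr)
  n_false <- n_called - n_true
  n_exp <- sum(tr)
  n_neg <- sum(!tr)
  structure(list(
    n_expected_sfp = n_exp, n_called = n_called, n_true = n_true,
    n_false = n_false,
    sensitivity = if (n_exp > 0) n_true / n_exp else NA_real_,
    fpr = if (n_called > 0) n_false / n_called else 0,
    fpr_conventional = if (n_neg > 0) n_false / n_neg else NA_real_
  ), class = "sfp_eval")
}

#' @export
print.sfp_eval <- function(x, ...) {
  cat(sprintf("SFP evaluation: %d called (%d true, %d false) of %d expected SFPs\n",
              x$n_called, x$n_true, x$n_false, x$n_expected_sfp))
  cat(sprintf("  sensitivity %.2f%%, false-call rate %.2f%% (1-specificity %.3g)\n",
              100 * x$sensitivity, 100 * x$fpr, x$fpr_conventional))
  invisible(x)
}

#' @method as.data.frame sfp_eval
#' @export
as.data.frame.sfp_eval <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' ROC curve over nested call sets
#'
#' Builds one evaluation point per threshold, ordered strict to loose.
#' Input is either a list of nested `sfp_calls` (each a superset of the
#' previous; verified) or a per-probe statistic table thresholded
#' directly. Sensitivity is checked to be non-decreasing as the
#' threshold relaxes.
#'
#' @param x a list of `sfp_calls` (ordered strict to loose) or a
#'   data.frame with `probe_id` and `statistic`.
#' @param truth truth table as in [evaluate_calls()].
#' @param thresholds thresholds to apply when `x` is a statistic table.
#' @param lower_is_call when thresholding a statistic table, call probes
#'   with `statistic <= threshold` (default) rather than `>=`.
#' @return an object of class `sfp_roc`: data.frame with `threshold`,
#'   `n_called`, `n_true`, `n_false`, `sensitivity`, `fpr`.
#' @export
roc_curve <- function(x, truth, thresholds = NULL, lower_is_call = TRUE) {
  if (is.data.frame(x)) {
    stopifnot(!is.null(thresholds),
              all(c("probe_id", "statistic") %in% names(x)))
    thresholds <- if (lower_is_call) sort(thresholds)
    else sort(thresholds, decreasing = TRUE)
    calls_list <- lapply(thresholds, function(th) {
      hit <- if (lower_is_call) x$statistic <= th else x$statistic >= th
      data.frame(probe_id = x$probe_id, called = !is.na(hit) & hit)
    })
  } else {
    stopifnot(is.list(x), length(x) >= 1, is.data.frame(x[[1]]))
    calls_list <- x
    thresholds <- vapply(x, function(cs)
      as.numeric(attr(cs, "threshold") %||% NA_real_), numeric(1))
    prev <- NULL
    for (cs in calls_list) {
      cur <- cs$probe_id[cs$called]
      if (!is.null(prev) && !all(prev %in% cur))
        stop("call sets are not nested from strict to loose")
      prev <- cur
    }
  }
  rows <- lapply(calls_list, function(cs)
    as.data.frame(evaluate_calls(cs, truth)))
  out <- do.call(rbind, rows)
  out <- cbind(threshold = thresholds, out)
  if (is.unsorted(out$sensitivity))
    stop("sensitivity must be non-decreasing along the curve")
  class(out) <- c("sfp_roc", "data.frame")
  out
}

#' @export
print.sfp_roc <- function(x, ...) {
  cat(sprintf("ROC curve with %d points (sensitivity %.3f..%.3f, fpr %.3f..%.3f)\n",
              nrow(x), min(x$sensitivity), max(x$sensitivity),
              min(x$fpr), max(x$fpr)))
  invisible(x)
}

#' @export
plot.sfp_roc <- function(x, add = FALSE, col = 1, ...) {
  if (!add) {
    plot.default(x$fpr, x$sensitivity, type = "l", col = col,
                 xlab = "false-call rate", ylab = "sensitivity",
                 xlim = c(0, max(x$fpr, 0.5)), ylim = c(0, 1), ...)
    abline(0, 1, lty = 3, col = "grey")
  } else lines(x$fpr, x$sensitivity, col = col, ...)
  invisible(x)
}

#' Slope-1 optimal threshold of a ROC curve
#'
#' Walks the curve from the strict end and returns the threshold at which
#' the secant slope (delta sensitivity / delta fpr) between adjacent
#' points first reaches 1 or below, i.e. where an extra false call stops
#' buying at least one extra true call. Ties break toward the stricter
#' threshold; if the slope never crosses 1 the loose end is returned with
#' a warning.
#'
#' @param roc an `sfp_roc` curve with at least 3 points.
#' @return the selected threshold.
#' @export
optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "sfp_roc"), nrow(roc) >= 3)
  dsens <- diff(roc$sensitivity)
  dfpr <- diff(roc$fpr)
  slope <- ifelse(dfpr == 0, Inf, dsens / dfpr)
  hit <- which(slope <= 1)
  if (length(hit) == 0) {
    warning("ROC slope never crosses 1; returning the loose end")
    return(roc$threshold[nrow(roc)])
  }
  roc$threshold[hit[1]]
}

#' Overlapping-bin intensity distributions and the PM > MM fraction
#'
#' Counts PM and MM probes in overlapping log10-intensity windows
#' (default width 0.1, step 0.05) of the per-probe mean log10 intensity,
#' and reports the fraction of probe pairs whose mean PM exceeds the
#' mean MM.
#'
#' @param x a `log_intensity_matrix`.
#' @param binwidth window width in log10 units.
#' @param step step between window starts.
#' @param strain restrict to one strain's replicates (default "A";
#'   `NULL` uses all samples).
#' @return a list with `bins` (data.frame: `bin_start`, `bin_end`,
#'   `pm_count`, `mm_count`) and `pm_gt_mm_fraction`.
#' @export
intensity_summary <- function(x, binwidth = 0.1, step = 0.05,
                              strain = "A") {
  stopifnot(inherits(x, "log_intensity_matrix"))
  cols <- if (is.null(strain)) seq_len(ncol(x$log10))
  else which(x$samples$strain == strain)
  pm <- rowMeans(pm_matrix(x)[, cols, drop = FALSE])
  mm <- rowMeans(mm_matrix(x)[, cols, drop = FALSE])
  lo <- floor(min(pm, mm) / step) * step - (binwidth - step)
  hi <- max(pm, mm)
  starts <- seq(lo, hi, by = step)
  count_in <- function(v) vapply(starts, function(b)
    sum(v >= b & v < b + binwidth), numeric(1))
  list(bins = data.frame(bin_start = starts, bin_end = starts + binwidth,
                         pm_count = count_in(pm), mm_count = count_in(mm)),
       pm_gt_mm_fraction = mean(pm > mm))
}

#' Fraction of significant PM/MM pairs per intensity bin
#'
#' Bins probe pairs by mean PM log10 intensity and reports, per bin, the
#' fraction with a significant PM vs MM difference (p < `p_cut`); the
#' curve supports choosing the expression cutoff below which SFP calling
#' is unreliable.
#'
#' @param pairs output of [pm_mm_pair_test()].
#' @param binwidth intensity bin width (default 0.1, non-overlapping).
#' @param p_cut significance cutoff (default 0.05).
#' @return data.frame with `bin_start`, `bin_end`, `n_pairs`,
#'   `frac_significant` (NA for empty bins).
#' @export
pm_mm_significance_by_bin <- function(pairs, binwidth = 0.1,
                                      p_cut = 0.05) {
  stopifnot(all(c("p", "pm_mean") %in% names(pairs)))
  lo <- floor(min(pairs$pm_mean) / binwidth) * binwidth
  hi <- max(pairs$pm_mean)
  starts <- seq(lo, hi, by = binwidth)
  n <- frac <- numeric(length(starts))
  for (i in seq_along(starts)) {
    ix <- pairs$pm_mean >= starts[i] & pairs$pm_mean < starts[i] + binwidth
    n[i] <- sum(ix)
    frac[i] <- if (n[i] > 0) mean(pairs$p[ix] < p_cut) else NA_real_
  }
  data.frame(bin_start = starts, bin_end = starts + binwidth,
             n_pairs = n, frac_significant = frac)
}

#' Sliding-window genome track of probes, truth, and calls
#'
#' Left-aligned 0-based half-open sliding windows (default 1 Mb window,
#' 0.1 Mb step) over the probe coordinates; per window, counts of probes,
#' sequence-predicted SFPs, correctly and falsely called SFPs, and window
#' sensitivity (missing when the window holds no predicted SFP). Trailing
#' partial windows keep their true width.
#'
#' @param probes probe table with `chrom` and `start`.
#' @param truth truth table (`probe_id`, `sfp_truth`).
#' @param calls call set (`probe_id`, `called`).
#' @param window window width in bp (default 1e6; must be positive).
#' @param step step width in bp (default 1e5).
#' @param chrom_length chromosome length; defaults to the last probe end.
#' @return an object of class `sfp_window_track`: data.frame with
#'   `chrom`, `start`, `end`, `n_probes`, `n_sfp`, `n_true_call`,
#'   `n_false_call`, `sensitivity`.
#' @export
window_track <- function(probes, truth, calls, window = 1e6,
                         step = 1e5, chrom_length = NULL) {
  if (window <= 0) stop("window must be positive")
  tr <- truth$sfp_truth[match(probes$probe_id, truth$probe_id)]
  cl <- calls$called[match(probes$probe_id, calls$probe_id)]
  if (anyNA(tr) || anyNA(cl))
    stop("truth/calls do not cover all probes")
  plen <- nchar(probes$pm_sequence %||% "")
  if (all(is.na(plen)) || length(plen) == 0) plen <- 25
  out <- lapply(unique(probes$chrom), function(ch) {
    on_ch <- probes$chrom == ch
    pos <- probes$start[on_ch]
    trc <- tr[on_ch]; clc <- cl[on_ch]
    clen <- chrom_length %||% max(pos + 25)
    starts <- seq(0, max(0, clen - 1), by = step)
    starts <- starts[starts < clen]
    ends <- pmin(starts + window, clen)
    n <- ns <- nt <- nf <- numeric(length(starts))
    for (i in seq_along(starts)) {
      ix <- pos >= starts[i] & pos < ends[i]
      n[i] <- sum(ix)
      ns[i] <- sum(trc[ix])
      nt[i] <- sum(clc[ix] & trc[ix])
      nf[i] <- sum(clc[ix] & !trc[ix])
    }
    data.frame(chrom = ch, start = starts, end = ends, n_probes = n,
               n_sfp = ns, n_true_call = nt, n_false_call = nf,
               sensitivity = ifelse(ns > 0, nt / ns, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("sfp_window_track", "data.frame")
  out
}

#' @export
print.sfp_window_track <- function(x, ...) {
  cat(sprintf("Sliding-window track: %d windows over %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  cat(sprintf("  genome-wide means per window: %.1f probes, %.1f predicted SFPs, %.1f true and %.1f false calls\n",
              mean(x$n_probes), mean(x$n_sfp), mean(x$n_true_call),
              mean(x$n_false_call)))
  if (any(!is.na(x$sensitivity)))
    cat(sprintf("  mean window sensitivity (where defined): %.3f\n",
                mean(x$sensitivity, na.rm = TRUE)))
  invisible(x)
}

#' Binomial clustering test for false-positive calls per probe set
#'
#' Under independent false calls at per-probe probability `p`, the number
#' of sets with exactly k false positives is
#' \eqn{\sum_{sets} \binom{n_{set}}{k} p^k (1-p)^{n_{set}-k}}, with
#' \eqn{n_{set}} the probes at risk of a false call (non-SFP probes) in
#' the set. Clustered false positives (e.g. from amplification
#' polymorphisms suppressing a whole 100-250 bp fragment) show up as an
#' excess of sets with k >= 2 over this expectation; a chi-square summary
#' over the k bins is reported.
#'
#' @param calls call set (`probe_id`, `called`).
#' @param truth truth table (`probe_id`, `sfp_truth`).
#' @param sets set label per probe of `truth`'s universe (named by
#'   probe_id, or aligned with `truth`).
#' @param p per-probe false-call probability; defaults to the observed
#'   false-call fraction among non-SFP probes. Must lie in (0, 1).
#' @return an object of class `sfp_fp_cluster`: list with `k`,
#'   `observed`, `expected`, `chisq`, `df`, `p_value`, and the `p` used.
#' @export
fp_cluster_test <- function(calls, truth, sets, p = NULL) {
  if (is.null(names(sets))) names(sets) <- truth$probe_id
  tr <- setNames(truth$sfp_truth, truth$probe_id)
  cl <- setNames(calls$called, calls$probe_id)
  ids <- truth$probe_id
  at_risk <- ids[!tr[ids]]
  false_call <- cl[at_risk]
  if (is.null(p)) p <- mean(false_call)
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("false-call probability p must lie strictly in (0, 1)")
  set_of <- sets[at_risk]
  n_set <- table(set_of)
  k_obs <- tapply(false_call, set_of, sum)
  kmax <- max(c(k_obs, 3))
  k <- 0:kmax
  observed <- vapply(k, function(kk) sum(k_obs == kk), numeric(1))
  expected <- vapply(k, function(kk)
    sum(dbinom(kk, as.integer(n_set), p)), numeric(1))
  # chi-square over bins, pooling the sparse tail (expected < 5)
  pool <- which(cumsum(rev(expected)) >= 5)[1]
  cutk <- length(k) - (if (is.na(pool)) 0 else pool - 1)
  oc <- c(observed[seq_len(max(cutk - 1, 1))],
          sum(observed[-seq_len(max(cutk - 1, 1))]))
  ec <- c(expected[seq_len(max(cutk - 1, 1))],
          sum(expected[-seq_len(max(cutk - 1, 1))]))
  keep <- ec > 0
  chisq <- sum((oc[keep] - ec[keep])^2 / ec[keep])
  df <- max(sum(keep) - 1, 1)
  structure(list(k = k, observed = observed, expected = expected,
                 p = p, chisq = chisq, df = df,
                 p_value = pchisq(chisq, df, lower.tail = FALSE)),
            class = "sfp_fp_cluster")
}

#' @export
print.sfp_fp_cluster <- function(x, ...) {
  cat(sprintf("False-positive clustering vs binomial(p = %.4g): chisq = %.2f (df %d, p = %.3g)\n",
              x$p, x$chisq, x$df, x$p_value))
  tab <- rbind(observed = x$observed, expected = round(x$expected, 2))
  colnames(tab) <- paste0("k=", x$k)
  print(tab)
  invisible(x)
}
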