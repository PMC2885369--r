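mk_truth <- function(n_true, n_false) {
  data.frame(probe_id = sprintf("p%06d", seq_len(n_true + n_false)),
             sfp_truth = rep(c(TRUE, FALSE), c(n_true, n_false)))
}

test_that("evaluation counts conserve and ratios follow the definitions", {
  truth <- mk_truth(10, 90)
  calls <- data.frame(probe_id = truth$probe_id,
                      called = truth$sfp_truth)
  ev <- evaluate_calls(calls, truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$fpr, 0)

  calls$called <- FALSE
  ev0 <- evaluate_calls(calls, truth)
  expect_equal(ev0$sensitivity, 0)
  expect_equal(ev0$fpr, 0)  # 0/0 convention

  set.seed(2)
  for (i in 1:10) {
    calls$called <- runif(100) < 0.3
    ev <- evaluate_calls(calls, truth)
    expect_equal(ev$n_true + ev$n_false, ev$n_called)
    expect_equal(ev$sensitivity, ev$n_true / 10)
  }

  expect_error(evaluate_calls(calls[1:50, ], truth), "universe")
})

test_that("ROC from a clean statistic reaches full sensitivity before errors", {
  truth <- mk_truth(20, 80)
  stat <- data.frame(probe_id = truth$probe_id,
                     statistic = ifelse(truth$sfp_truth,
                                        seq(0.01, 0.2, length.out = 20),
                                        seq(0.5, 1, length.out = 80)))
  roc <- roc_curve(stat, truth, thresholds = c(0.005, 0.1, 0.3, 0.7, 1))
  expect_s3_class(roc, "sfp_roc")
  expect_false(is.unsorted(roc$sensitivity))
  at3 <- roc[roc$threshold == 0.3, ]
  expect_equal(at3$sensitivity, 1)
  expect_equal(at3$fpr, 0)
  # the negated statistic is anti-learning: it exhausts every false
  # probe before calling a single true one
  stat2 <- transform(stat, statistic = -statistic)
  roc2 <- roc_curve(stat2, truth, thresholds = -c(1, 0.7, 0.3, 0.1, 0.005))
  expect_true(all(roc2$sensitivity[roc2$n_called <= 80] == 0))
  expect_true(all(roc2$fpr[roc2$n_called > 0 & roc2$n_called <= 80] == 1))
})

test_that("a random statistic yields fpr near one minus prevalence", {
  fprs <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      truth <- mk_truth(100, 100)
      stat <- data.frame(probe_id = truth$probe_id,
                         statistic = runif(200))
      roc <- roc_curve(stat, truth, thresholds = 0.5)
      roc$fpr
    })
  }, numeric(1))
  expect_lt(abs(mean(fprs) - 0.5), 0.05)
})

test_that("non-nested call-set lists are rejected", {
  truth <- mk_truth(5, 5)
  cs1 <- data.frame(probe_id = truth$probe_id,
                    called = c(TRUE, rep(FALSE, 9)))
  cs2 <- data.frame(probe_id = truth$probe_id,
                    called = c(FALSE, TRUE, rep(FALSE, 8)))
  expect_error(roc_curve(list(cs1, cs2), truth), "nested")
})

test_that("slope-1 threshold selection finds the first unit-slope secant", {
  # constructed curve with adjacent-secant slopes 3, 2, 1, 0.5
  roc <- data.frame(threshold = c(5, 4, 3, 2, 1),
                    n_called = 1:5, n_true = 1:5, n_false = 0,
                    sensitivity = c(0, 0.3, 0.5, 0.6, 0.65),
                    fpr = c(0, 0.1, 0.2, 0.3, 0.4))
  class(roc) <- c("sfp_roc", "data.frame")
  expect_equal(optimal_threshold(roc), 3)

  # strictly concave curve: unique crossing
  fpr <- seq(0, 1, by = 0.1)
  sens <- sqrt(fpr)
  roc2 <- data.frame(threshold = rev(seq_along(fpr)), sensitivity = sens,
                     fpr = fpr)
  class(roc2) <- c("sfp_roc", "data.frame")
  slopes <- diff(sens) / diff(fpr)
  expected <- rev(seq_along(fpr))[which(slopes <= 1)[1]]
  expect_equal(optimal_threshold(roc2), expected)

  # slope never reaching 1: warn and return the loose end
  roc3 <- data.frame(threshold = c(3, 2, 1),
                     sensitivity = c(0, 0.4, 0.9), fpr = c(0, 0.1, 0.2))
  class(roc3) <- c("sfp_roc", "data.frame")
  expect_warning(th <- optimal_threshold(roc3), "never")
  expect_equal(th, 1)
})

test_that("optimal SAM delta maximizes sensitivity minus fpr on a grid", {
  p <- sim_params(noise_sd = 0.15, sfp_effect_mean = 0.4)
  sim <- small_gdna_sim(n_sets = 80, seed = 101, params = p)
  fit <- sam_fit(sim$lm, seed = 102)
  deltas <- seq(1.4, 0.05, by = -0.05)
  csl <- lapply(deltas, function(dd) sam_call(fit, delta = dd))
  roc <- roc_curve(csl, sim$truth)
  th <- optimal_threshold(roc)
  youden <- roc$sensitivity - roc$fpr
  best <- roc$threshold[which.max(youden)]
  # the slope-1 point sits within one grid step of the Youden optimum
  expect_lte(abs(th - best), 0.051)
})

test_that("overlapping intensity bins tile correctly and separate PM from MM", {
  p <- sim_params(snp_rate = 0, indel_rate = 0, mm_penalty = 1.5,
                  noise_sd = 0.02, saturation_ceiling = Inf)
  sim <- small_gdna_sim(n_sets = 20, seed = 111, params = p)
  s <- intensity_summary(sim$lm)
  expect_equal(s$bins$bin_end - s$bins$bin_start,
               rep(0.1, nrow(s$bins)))
  # every probe lands in exactly binwidth/step = 2 windows
  expect_equal(sum(s$bins$pm_count), 2 * nrow(sim$probes))
  expect_equal(sum(s$bins$mm_count), 2 * nrow(sim$probes))
  expect_equal(s$pm_gt_mm_fraction, 1)
})

test_that("with no MM penalty the PM > MM fraction is one half", {
  fr <- vapply(1:20, function(s) {
    p <- sim_params(snp_rate = 0, indel_rate = 0, mm_penalty = 0,
                    noise_sd = 0.1, saturation_ceiling = Inf)
    sim <- small_gdna_sim(n_sets = 15, seed = 300 + s, params = p)
    intensity_summary(sim$lm)$pm_gt_mm_fraction
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 3 * sqrt(0.25 / (20 * 165)))
})

test_that("PM/MM significance rises with intensity when separation does", {
  pairs <- data.frame(probe_id = sprintf("p%03d", 1:300),
                      p = c(runif(150), runif(150, 0, 0.01)),
                      pm_mean = c(runif(150, 1.6, 2.4),
                                  runif(150, 2.6, 3.4)))
  bins <- pm_mm_significance_by_bin(pairs)
  lo <- bins$frac_significant[bins$bin_end <= 2.5]
  hi <- bins$frac_significant[bins$bin_start >= 2.5]
  expect_gt(mean(hi, na.rm = TRUE), 0.9)
  expect_lt(mean(lo, na.rm = TRUE), 0.3)
  # single-pair bins are 0 or 1; empty bins are missing
  one <- data.frame(probe_id = "x", p = 0.2, pm_mean = 2.0)
  b1 <- pm_mm_significance_by_bin(one)
  expect_true(all(b1$frac_significant[b1$n_pairs == 1] %in% c(0, 1)))
  pairs2 <- data.frame(probe_id = c("a", "b"), p = c(0.5, 0.001),
                       pm_mean = c(1.0, 2.0))
  b2 <- pm_mm_significance_by_bin(pairs2)
  expect_true(any(is.na(b2$frac_significant)))
})

test_that("window tracks count positions independent of probe order", {
  set.seed(5)
  n <- 500
  probes <- data.frame(probe_id = sprintf("p%04d", 1:n),
                       chrom = "chr1",
                       start = sort(sample(0:99975, n)),
                       pm_sequence = strrep("A", 25))
  truth <- data.frame(probe_id = probes$probe_id,
                      sfp_truth = runif(n) < 0.1)
  calls <- data.frame(probe_id = probes$probe_id,
                      called = truth$sfp_truth & runif(n) < 0.8)
  wt <- window_track(probes, truth, calls, window = 10000, step = 5000,
                     chrom_length = 100000)
  full <- wt[wt$end - wt$start == 10000, ]
  # roughly uniform density: each full window holds about n/10 probes
  expect_lt(max(abs(full$n_probes - n / 10)), 4 * sqrt(n / 10))
  # shuffling probe order changes nothing
  ix <- sample(n)
  wt2 <- window_track(probes[ix, ], truth, calls, window = 10000,
                      step = 5000, chrom_length = 100000)
  expect_equal(wt2, wt)
  # windows without predicted SFPs have missing sensitivity
  wt3 <- window_track(probes, transform(truth, sfp_truth = FALSE),
                      calls, window = 10000, step = 5000)
  expect_true(all(is.na(wt3$sensitivity)))
  expect_error(window_track(probes, truth, calls, window = 0), "positive")
})

test_that("all SFPs in one window localize the defined sensitivity", {
  probes <- data.frame(probe_id = sprintf("p%d", 1:40), chrom = "chr1",
                       start = seq(0, 39000, by = 1000),
                       pm_sequence = strrep("A", 25))
  truth <- data.frame(probe_id = probes$probe_id,
                      sfp_truth = probes$start < 5000)
  calls <- data.frame(probe_id = probes$probe_id,
                      called = truth$sfp_truth)
  wt <- window_track(probes, truth, calls, window = 5000, step = 5000,
                     chrom_length = 40000)
  expect_equal(which(!is.na(wt$sensitivity)), 1L)
  expect_equal(wt$sensitivity[1], 1)
})

test_that("independent false calls match the binomial set expectation", {
  n_sets <- 200; per_set <- 11; p_fc <- 0.05
  obs_mat <- vapply(1:20, function(s) {
    withr::with_seed(400 + s, {
      truth <- data.frame(probe_id = sprintf("p%05d", 1:(n_sets * per_set)),
                          sfp_truth = FALSE)
      sets <- rep(sprintf("s%03d", 1:n_sets), each = per_set)
      calls <- data.frame(probe_id = truth$probe_id,
                          called = runif(nrow(truth)) < p_fc)
      fc <- fp_cluster_test(calls, truth, sets, p = p_fc)
      obs <- rep(0, 6)
      take <- min(6, length(fc$observed))
      obs[1:take] <- fc$observed[1:take]
      obs
    })
  }, numeric(6))
  expected <- n_sets * dbinom(0:5, per_set, p_fc)
  for (k in 1:4) {
    sd_k <- sqrt(n_sets * dbinom(k - 1, per_set, p_fc) *
                   (1 - dbinom(k - 1, per_set, p_fc)) / 20)
    expect_lt(abs(mean(obs_mat[k, ]) - expected[k]), 3 * sd_k)
  }
})

test_that("clustering test flags planted clusters and guards p", {
  truth <- data.frame(probe_id = sprintf("p%04d", 1:1100),
                      sfp_truth = FALSE)
  sets <- rep(sprintf("s%03d", 1:100), each = 11)
  # clustered: 10 sets get 4 false calls each
  called <- rep(FALSE, 1100)
  withr::with_seed(7, {
    for (s in sample(100, 10)) {
      called[which(sets == sprintf("s%03d", s))[1:4]] <- TRUE
    }
  })
  calls <- data.frame(probe_id = truth$probe_id, called = called)
  fc <- fp_cluster_test(calls, truth, sets)
  expect_gt(sum(fc$observed[fc$k >= 2]), sum(fc$expected[fc$k >= 2]))
  expect_lt(fc$p_value, 0.01)

  calls$called <- FALSE
  expect_error(fp_cluster_test(calls, truth, sets), "strictly in")
  fc0 <- fp_cluster_test(calls, truth, sets, p = 0.01)
  expect_equal(fc0$observed[fc0$k == 0], 100)
  expect_equal(sum(fc0$observed[fc0$k > 0]), 0)
})
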