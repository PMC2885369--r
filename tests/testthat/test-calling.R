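make_mat <- function(n, reps = 4, mean = 3, sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * 2 * reps, mean, sd), n, 2 * reps)
    rownames(m) <- sprintf("p%05d", seq_len(n))
    m
  })
}
strains_of <- function(reps = 4) rep(c("A", "B"), each = reps)

test_that("log transform floors at 1 raw unit and round-trips powers", {
  expect_equal(log_transform(matrix(1000)), matrix(3))
  expect_equal(log_transform(matrix(0)), matrix(0))
  x <- matrix(10^c(0, 1.5, 4.2))
  expect_equal(log_transform(x), matrix(c(0, 1.5, 4.2)))
  expect_error(log_transform(matrix(-1)), "negative")
})

test_that("SAM statistic is zero on identical strains and antisymmetric", {
  m <- make_mat(200)
  mm <- cbind(m[, 1:4], m[, 1:4])
  st <- sam_statistic(mm, s0 = 0.1, strain = strains_of())
  expect_true(all(st$d == 0))

  st1 <- sam_statistic(m, s0 = 0.1, strain = strains_of())
  st2 <- sam_statistic(m, s0 = 0.1, strain = rev(strains_of()))
  expect_equal(st1$d, -st2$d)
})

test_that("SAM statistic matches an independently coded oracle", {
  m <- make_mat(500, seed = 8)
  st <- sam_statistic(m, s0 = 0.05, strain = strains_of())
  d_oracle <- sam_oracle_d(m, strains_of() == "B", s0 = 0.05)
  expect_equal(st$d, unname(d_oracle), tolerance = 1e-12)
})

test_that("fudge factor selection is guarded and scale-equivariant", {
  m <- make_mat(400, seed = 2)
  st <- sam_statistic(m, strain = strains_of())
  r <- st$r; s <- st$s
  expect_warning(s0c <- choose_s0(r, rep(0.2, 400)), "equal")
  expect_equal(s0c, 0.2 * 0.05)
  # scaling data by 10 scales s0 by 10, leaving d invariant
  s0a <- choose_s0(r, s)
  s0b <- choose_s0(10 * r, 10 * s)
  expect_equal(s0b, 10 * s0a, tolerance = 1e-12)
  expect_equal(r / (s + s0a), (10 * r) / (10 * s + s0b),
               tolerance = 1e-12)
})

test_that("on homoscedastic null data the chosen s0 behaves like a percentile", {
  fracs <- vapply(1:5, function(sd) {
    m <- make_mat(2000, mean = 3, sd = 0.1, seed = sd + 10)
    st <- sam_statistic(m, strain = strains_of())
    s0m <- unname(quantile(st$s, 0.5))
    f1 <- sam_call(sam_fit(m, strain = strains_of(),
                           s0 = attr(st, "s0")), delta = 0.4)
    f2 <- sam_call(sam_fit(m, strain = strains_of(), s0 = s0m),
                   delta = 0.4)
    abs(mean(f1$called) - mean(f2$called))
  }, numeric(1))
  # null false-call fractions agree within simulation error
  expect_lt(mean(fracs), 0.01)
})

test_that("SAM calls nest in delta and vanish at infinite delta", {
  p <- sim_params(noise_sd = 0.1, sfp_effect_mean = 0.5)
  sim <- small_gdna_sim(n_sets = 60, seed = 71, params = p)
  fit <- sam_fit(sim$lm, seed = 72)
  expect_equal(sum(sam_call(fit, delta = Inf)$called), 0)
  deltas <- c(1.2, 0.8, 0.4, 0.2, 0.1)
  called <- lapply(deltas, function(dd) {
    cs <- sam_call(fit, delta = dd)
    cs$probe_id[cs$called]
  })
  for (i in seq_along(deltas)[-1]) {
    expect_true(all(called[[i - 1]] %in% called[[i]]),
                info = paste("delta", deltas[i - 1], "vs", deltas[i]))
  }
})

test_that("a planted strong deficit outranks every null probe in SAM", {
  m <- make_mat(300, sd = 0.05, seed = 3)
  m[1, 5:8] <- m[1, 5:8] - 0.5
  fit <- sam_fit(m, strain = strains_of())
  expect_equal(which.min(fit$stat$d), 1L)
  cs <- sam_call(fit, delta = 0.9)
  expect_true(cs$called[1])
  expect_equal(cs$direction[1], "loss")
})

test_that("SAM requires replicate structure", {
  m <- matrix(rnorm(20), 10, 2, dimnames = list(letters[1:10], NULL))
  expect_error(sam_statistic(m, strain = c("A", "B")), "replicate")
})

test_that("ANOVA F equals the squared t and respects sidedness", {
  m <- make_mat(300, seed = 4)
  cs <- anova_call(m, alpha = 0.01, strain = strains_of())
  expect_equal(cs$F, cs$t^2, tolerance = 1e-12)
  # cross-check a handful of probes against stats::t.test
  for (i in c(1, 50, 299)) {
    tt <- stats::t.test(m[i, 5:8], m[i, 1:4], var.equal = TRUE,
                        alternative = "less")
    expect_equal(cs$statistic[i], tt$p.value, tolerance = 1e-12)
  }
  # identical groups: uninformative, never called
  mm <- cbind(m[, 1:4], m[, 1:4])
  cs0 <- anova_call(mm, alpha = 0.49, strain = strains_of())
  expect_equal(sum(cs0$called), 0)
  # zero within-group variance: identical constants give p = 1; an exact
  # separation gives p = 0 flagged as degenerate
  cm <- matrix(c(rep(3, 8), rep(3, 4), rep(2.5, 4)), 2, 8, byrow = TRUE,
               dimnames = list(c("same", "shift"), NULL))
  csd <- anova_call(cm, alpha = 0.49, strain = strains_of())
  expect_true(all(csd$degenerate))
  expect_equal(csd$statistic, c(1, 0))
  expect_equal(csd$called, c(FALSE, TRUE))
})

test_that("a planted half-log deficit is overwhelmingly significant", {
  m <- make_mat(100, sd = 0.05, seed = 5)
  m[1, 5:8] <- m[1, 5:8] - 0.5
  cs <- anova_call(m, alpha = 1e-4, strain = strains_of())
  expect_lt(cs$statistic[1], 1e-4)
  expect_true(cs$called[1])
})

test_that("random pseudo-set grouping is deterministic with sane remainders", {
  ids <- sprintf("p%04d", 1:1000)
  g <- group_random(ids, 500, seed = 9)
  expect_equal(as.integer(sort(table(g))), c(500, 500))
  expect_identical(g, group_random(ids, 500, seed = 9))
  expect_false(identical(g, group_random(ids, 500, seed = 10)))
  # remainder below 50 merges into the last group
  g2 <- group_random(sprintf("p%04d", 1:1001), 500, seed = 9)
  expect_equal(as.integer(sort(table(g2))), c(500, 501))
  # remainder of at least 50 stands alone
  g3 <- group_random(sprintf("p%04d", 1:1050), 500, seed = 9)
  expect_equal(as.integer(sort(table(g3))), c(50, 500, 500))
  expect_warning(g4 <- group_random(ids[1:100], 500), "single group")
  expect_equal(as.integer(table(g4)), 100)
})

test_that("SNEP calls within-set outliers and is location-equivariant", {
  m <- make_mat(22, sd = 0.03, seed = 6)
  sets <- rep(c("s1", "s2"), each = 11)
  # plant an outlier: probe 1 loses far more than 10 robust scales in B
  m[1, 5:8] <- m[1, 5:8] - 1.0
  cs <- snep_call(m, alpha = 1e-6, sets = sets, strain = strains_of())
  expect_true(cs$called[1])
  expect_equal(sum(cs$called), 1)
  expect_equal(cs$direction[1], "loss")
  # adding a set-wide constant to strain B changes nothing
  m2 <- m
  m2[sets == "s1", 5:8] <- m2[sets == "s1", 5:8] + 5
  cs2 <- snep_call(m2, alpha = 1e-6, sets = sets, strain = strains_of())
  expect_identical(cs$called, cs2$called)
})

test_that("SNEP skips degenerate sets and stays quiet on constant input", {
  m <- matrix(3, 11, 8, dimnames = list(sprintf("p%d", 1:11), NULL))
  expect_warning(cs <- snep_call(m, alpha = 0.49,
                                 sets = rep("s1", 11),
                                 strain = strains_of()), "zero")
  expect_equal(sum(cs$called), 0)
})

test_that("SNEP thresholds nest", {
  p <- sim_params(noise_sd = 0.1)
  sim <- small_gdna_sim(n_sets = 50, seed = 81, params = p)
  alphas <- 10^c(-18, -11.25, -10.05, -6, -3)
  called <- lapply(alphas, function(a) {
    cs <- snep_call(sim$lm, alpha = a)
    cs$probe_id[cs$called]
  })
  for (i in seq_along(alphas)[-1]) {
    expect_true(all(called[[i - 1]] %in% called[[i]]))
  }
})

test_that("SNEP tail calls on null data stay within the robust-scale
           inflation bound", {
  p <- sim_params(snp_rate = 0, indel_rate = 0)
  gp <- generate_genome_pair(250000, p, seed = 201)
  pr <- design_probe_sets(gp, 455, seed = 202)
  alpha <- 0.01
  rates <- vapply(1:5, function(s) {
    im <- simulate_intensities(pr, gp, "gdna", 5, p, seed = 210 + s)
    cs <- snep_call(log_transform(im), alpha = alpha,
                    sets = group_random(pr$probe_id, 500, seed = s))
    mean(cs$called)
  }, numeric(1))
  # MAD small-sample bias inflates the tail by at most a factor of 2
  expect_lt(mean(rates), 2 * alpha)
  expect_gt(mean(rates), alpha / 2)
})

test_that("expression filtering requires the cutoff in both strains", {
  m <- rbind(matrix(2.6, 5, 8), matrix(c(rep(2.6, 4), rep(2.4, 4)),
                                       5, 8, byrow = TRUE))
  rownames(m) <- sprintf("p%d", 1:10)
  sets <- rep(c("hi", "split"), each = 5)
  expect_identical(expression_filter(m, cutoff = 2.5, sets = sets,
                                     strain = strains_of()), "hi")
  expect_setequal(expression_filter(m, cutoff = 0, sets = sets,
                                    strain = strains_of()),
                  c("hi", "split"))
})

test_that("PM/MM pair tests separate planted penalties and are exchangeable", {
  p0 <- sim_params(snp_rate = 0, indel_rate = 0, mm_penalty = 1.0,
                   noise_sd = 0.05, saturation_ceiling = Inf)
  sim <- small_gdna_sim(n_sets = 10, seed = 91, params = p0)
  pt <- pm_mm_pair_test(sim$lm)
  expect_true(all(pt$p < 0.05))
  expect_true(all(pt$t < 0))  # t is signed MM minus PM: MM sits below PM

  # no penalty: PM and MM exchangeable, p roughly uniform
  p1 <- sim_params(snp_rate = 0, indel_rate = 0, mm_penalty = 0,
                   noise_sd = 0.05, saturation_ceiling = Inf)
  sim1 <- small_gdna_sim(n_sets = 30, seed = 92, params = p1)
  pt1 <- pm_mm_pair_test(sim1$lm)
  expect_lt(abs(mean(pt1$p < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / nrow(pt1)))

  # permuting replicate columns leaves the p-values unchanged
  lm2 <- sim$lm
  ord <- c(4:1, 5:8)
  lm2$log10 <- lm2$log10[, ord]
  lm2$samples <- lm2$samples[ord, ]
  expect_equal(pm_mm_pair_test(lm2)$p, pt$p, tolerance = 1e-12)
})
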