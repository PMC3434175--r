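test_that("median_abs_error is a median of absolute differences", {
  x <- sin(seq(0, 10, 0.1))
  expect_equal(median_abs_error(x, x), 0)
  # constant offset passes straight through (the reported post-training
  # mean error magnitude used as the offset)
  expect_equal(median_abs_error(x, x + 0.39), 0.39)
  expect_equal(median_abs_error(c(0, 0, 0), c(0, 1, 100)), 1)
  expect_error(median_abs_error(1:3, 1:4), "equal length")
})

make_additive_runs <- function(n_subjects = 4, effects = c(e = 0, t = 0,
                                                           m = 0.1, d = 0),
                               base = 0.5, noise_sd = 0, seed = 1) {
  cells <- expand.grid(e = 0:1, t = 0:1, m = 0:1, d = 0:1)
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    y <- base - as.matrix(cells) %*% effects + rnorm(nrow(cells), 0, noise_sd)
    data.frame(subject_id = paste0("P", s), cells, median_abs_error = y)
  }))
}

test_that("main effects recover additive generating coefficients exactly", {
  # all cells equal: every difference is zero
  runs <- make_additive_runs(effects = c(e = 0, t = 0, m = 0, d = 0))
  me <- main_effects(runs)
  expect_equal(me$difference, rep(0, 4))
  # motion subtracts exactly 0.1 ft: motion difference 0.1, others 0
  runs <- make_additive_runs(effects = c(e = 0, t = 0, m = 0.1, d = 0))
  me <- main_effects(runs)
  expect_equal(me$difference[me$factor == "m"], 0.1)
  expect_equal(me$difference[me$factor != "m"], rep(0, 3))
  # a general additive pattern
  runs <- make_additive_runs(effects = c(e = 0.02, t = -0.03, m = 0.1,
                                         d = -0.25))
  expect_equal(main_effects(runs)$difference, c(0.02, -0.03, 0.1, -0.25))
})

test_that("incomplete or unbalanced designs are refused", {
  runs <- make_additive_runs()
  expect_error(main_effects(runs[-1, ]), "incomplete")
  expect_error(rm_anova(runs[-1, ]), "incomplete")
  dup <- rbind(runs, runs[1, ])
  expect_error(rm_anova(dup), "unbalanced")
  bad <- runs; bad$m[1] <- 2
  expect_error(rm_anova(bad), "two-level")
})

test_that("rm_anova matches a hand-worked two-subject table", {
  # subject 1: level0 = 1, level1 = 3; subject 2: level0 = 2, level1 = 6
  runs <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                     g = c(0, 1, 0, 1),
                     median_abs_error = c(1, 3, 2, 6))
  out <- rm_anova(runs, factors = "g")
  # SS_factor = 9, SS_interaction = 1, df = (1, 1) -> F = 9
  expect_equal(out$F, 9)
  expect_equal(out$df1, 1L); expect_equal(out$df2, 1L)
  expect_equal(out$p, pf(9, 1, 1, lower.tail = FALSE))
})

test_that("rm_anova agrees with aov's within-subject error stratum", {
  runs <- make_additive_runs(n_subjects = 6,
                             effects = c(e = 0, t = 0, m = 0.08, d = -0.2),
                             noise_sd = 0.05, seed = 4)
  ours <- rm_anova(runs)
  for (f in c("e", "t", "m", "d")) {
    agg <- aggregate(runs$median_abs_error,
                     list(subject = runs$subject_id, g = runs[[f]]), mean)
    a <- summary(aov(x ~ factor(g) + Error(factor(subject) / factor(g)),
                     data = agg))
    F_aov <- a[["Error: factor(subject):factor(g)"]][[1]]["factor(g)", "F value"]
    expect_equal(ours$F[ours$factor == f], F_aov, tolerance = 1e-8)
  }
})

test_that("for one factor F equals the squared paired t statistic", {
  for (seed in 1:5) {
    runs <- make_additive_runs(n_subjects = 8,
                               effects = c(e = 0, t = 0, m = 0.05, d = 0),
                               noise_sd = 0.08, seed = seed)
    out <- rm_anova(runs, factors = "m")
    m0 <- tapply(runs$median_abs_error[runs$m == 0],
                 runs$subject_id[runs$m == 0], mean)
    m1 <- tapply(runs$median_abs_error[runs$m == 1],
                 runs$subject_id[runs$m == 1], mean)
    tt <- paired_compare(m0, m1)
    expect_equal(out$F, tt$t^2, tolerance = 1e-9)
    expect_equal(out$df2, tt$df)
  }
})

test_that("a huge effect with tiny noise is overwhelmingly significant", {
  runs <- make_additive_runs(n_subjects = 6, effects = c(e = 0, t = 0,
                                                         m = 0.5, d = 0),
                             noise_sd = 1e-4, seed = 2)
  out <- rm_anova(runs)
  expect_lt(out$p[out$factor == "m"], 1e-6)
})

test_that("the null type-I error rate is calibrated at alpha = 0.05", {
  p_m <- vapply(1:1000, function(s) {
    runs <- make_additive_runs(n_subjects = 10,
                               effects = c(e = 0, t = 0, m = 0, d = 0),
                               noise_sd = 0.1, seed = 10000 + s)
    out <- rm_anova(runs, factors = "m")
    out$p
  }, numeric(1))
  expect_gte(mean(p_m < 0.05), 0.03)
  expect_lte(mean(p_m < 0.05), 0.07)
})

test_that("paired_compare matches hand calculation and conventions", {
  # textbook pairs: d = (-2, -2, -1), t = -5
  out <- paired_compare(c(10, 9, 11), c(12, 11, 12))
  expect_equal(out$t, -5, tolerance = 1e-9)
  expect_equal(out$df, 2)
  expect_equal(out$p, 2 * pt(-5, 2), tolerance = 1e-9)
  # one-sided direction
  out_l <- paired_compare(c(10, 9, 11), c(12, 11, 12), alternative = "less")
  expect_equal(out_l$p, pt(-5, 2), tolerance = 1e-9)
  # identical vectors: t = 0, p = 1 by convention
  out0 <- paired_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out0$t, 0); expect_equal(out0$p, 1)
  # constant nonzero differences: extreme t, vanishing p
  outc <- paired_compare(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(is.infinite(outc$t) && outc$t > 0)
  expect_equal(outc$p, 0)
  set.seed(1)
  outn <- paired_compare(1:4 + 1 + rnorm(4, 0, 1e-8), 1:4)
  expect_lt(outn$p, 1e-8)
  expect_error(paired_compare(1:3, 1:4), "equal length")
  expect_error(paired_compare(1, 1), "at least 2")
})

test_that("the learning filter applies the 0.15 ft improvement rule", {
  # exact line: improvement 0.3 -> included
  out <- learning_filter(c(0.9, 0.8, 0.7, 0.6))
  expect_true(out$included)
  expect_equal(out$improvement, 0.3, tolerance = 1e-12)
  expect_equal(out$slope, -0.1, tolerance = 1e-12)
  # flat: excluded
  expect_false(learning_filter(c(0.5, 0.5, 0.5, 0.5))$included)
  # noisy case against the explicit normal-equation solution
  y <- c(0.6, 0.5, 0.55, 0.46)
  ph <- 1:4
  slope <- sum((ph - mean(ph)) * (y - mean(y))) / sum((ph - mean(ph))^2)
  out <- learning_filter(y)
  expect_equal(out$slope, slope, tolerance = 1e-12)
  expect_equal(out$improvement, -3 * slope, tolerance = 1e-12)
  expect_identical(out$included, -3 * slope >= 0.15)
  expect_error(learning_filter(c(0.5, NA, 0.4, 0.3)), "finite")
})

test_that("steepening the learning slope never flips included to excluded", {
  set.seed(3)
  for (i in 1:20) {
    y <- runif(4, 0.3, 0.9)
    base <- learning_filter(y)
    steeper <- learning_filter(y - (0:3) * 0.05)  # strictly steeper descent
    if (base$included) expect_true(steeper$included)
    expect_gte(steeper$improvement, base$improvement)
  }
})

test_that("simulated factorial cohorts show the expected pre-training pattern", {
  runs <- simulate_factorial_runs(n_subjects = 5, duration = 40, dt = 0.02,
                                  seed = 31)
  me <- main_effects(runs)
  # motion helps; difficulty hurts; audio cues do nothing before training
  expect_gt(me$difference[me$factor == "m"], 0.02)
  expect_lt(me$difference[me$factor == "d"], -0.02)
  expect_lt(abs(me$difference[me$factor == "t"]),
            me$difference[me$factor == "m"])
})
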