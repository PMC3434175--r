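test_that("normalize_thresholds divides the bimodal by each unimodal", {
  uv <- normalize_thresholds(0.27, 0.21, 0.16)
  expect_equal(uv$u, 0.5926, tolerance = 1e-4)
  expect_equal(uv$v, 0.7619, tolerance = 1e-4)
  expect_equal(normalize_thresholds(1, 1, 1), data.frame(u = 1, v = 1))
  expect_equal(normalize_thresholds(2, 4, 1), data.frame(u = 0.5, v = 0.25))
  expect_error(normalize_thresholds(0, 1, 1), "T_a")
  expect_error(normalize_thresholds(1, -2, 1), "T_m")
})

test_that("predict_combined_threshold matches the Minkowski identity", {
  expect_equal(predict_combined_threshold(c(1, 1), 2), 1 / sqrt(2))
  expect_equal(predict_combined_threshold(c(1, 1), 1), 0.5)
  Tc <- predict_combined_threshold(c(0.27, 0.21), 2.1)
  expect_equal(Tc, 0.168, tolerance = 1e-2)
  # bisection cross-check on sum (T/T_i)^k = 1
  oracle <- uniroot(function(T) (T / 0.27)^2.1 + (T / 0.21)^2.1 - 1,
                    c(1e-6, 0.21), tol = 1e-12)$root
  expect_equal(Tc, oracle, tolerance = 1e-9)
  # combined threshold below the best single cue, approaching it as k grows
  expect_lt(predict_combined_threshold(c(0.3, 0.2), 4), 0.2)
  expect_equal(predict_combined_threshold(c(0.3, 0.2), 300), 0.2,
               tolerance = 1e-2)
  expect_error(predict_combined_threshold(numeric(0), 2), "at least one")
})

test_that("k_from_triple solves the pooling equation", {
  expect_equal(k_from_triple(0.27, 0.21, 0.16), 1.81, tolerance = 1e-2)
  expect_equal(k_from_triple(1, 1, 1 / sqrt(2)), 2, tolerance = 1e-6)
  expect_equal(k_from_triple(1, 1, 0.5), 1, tolerance = 1e-6)
  # residual of the defining equation is tiny
  k <- k_from_triple(0.27, 0.21, 0.16)
  expect_lt(abs((0.16 / 0.27)^k + (0.16 / 0.21)^k - 1), 1e-10)
})

test_that("k_from_triple flags absent facilitation", {
  expect_error(k_from_triple(0.27, 0.21, 0.22), "facilitation")
  expect_identical(k_from_triple(0.27, 0.21, 0.22, lenient = TRUE), Inf)
})

test_that("k_from_triple agrees with a brute-force grid scan", {
  grid <- seq(0.10, 64, by = 0.01)
  set.seed(99)
  for (i in 1:300) {
    tr <- random_triple()
    k_fit <- k_from_triple(tr$T_a, tr$T_m, tr$T_am)
    u <- tr$T_am / tr$T_a; v <- tr$T_am / tr$T_m
    k_grid <- grid[which.min(abs(u^grid + v^grid - 1))]
    expect_lt(abs(k_fit - k_grid), 0.011)  # within one grid step
  }
})

test_that("k is scale invariant and monotone in facilitation strength", {
  set.seed(5)
  for (i in 1:20) {
    tr <- random_triple()
    k0 <- k_from_triple(tr$T_a, tr$T_m, tr$T_am)
    for (c_scale in c(0.01, 3.7))
      expect_equal(k_from_triple(c_scale * tr$T_a, c_scale * tr$T_m,
                                 c_scale * tr$T_am), k0, tolerance = 1e-8)
    # deeper facilitation (smaller T_am) -> smaller k
    k_deeper <- k_from_triple(tr$T_a, tr$T_m, tr$T_am * 0.95)
    expect_lt(k_deeper, k0)
  }
})

test_that("the group fit recovers a noiseless Euclidean locus exactly", {
  th <- seq(0.1, pi / 2 - 0.1, length.out = 10)
  pts <- data.frame(u = cos(th), v = sin(th))  # on the k = 2 unit circle
  fit <- fit_pooling(pts)
  expect_equal(fit$k, 2, tolerance = 1e-4)
  expect_equal(fit$regime, "optimal")
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("a single point reduces the group fit to k_from_triple", {
  fit <- fit_pooling(data.frame(u = 0.5926, v = 0.7619))
  expect_equal(fit$k, k_from_triple(0.27, 0.21, 0.16), tolerance = 1e-3)
  # raw-threshold input is normalised internally
  fit2 <- fit_pooling(data.frame(subject_id = "S4", T_a = 0.27, T_m = 0.21,
                                 T_am = 0.16))
  expect_equal(fit2$k, k_from_triple(0.27, 0.21, 0.16), tolerance = 1e-9)
})

test_that("strict mode names non-facilitating subjects", {
  pts <- data.frame(subject_id = c("A", "B"),
                    u = c(0.6, 1.1), v = c(0.7, 1.2))
  expect_error(fit_pooling(pts), "B")
  fit <- fit_pooling(pts, strict = FALSE)
  expect_true(is.finite(fit$k))
})

test_that("regimes are classified by proximity with an independence cutoff", {
  expect_equal(classify_regime(1.05), "linear")
  expect_equal(classify_regime(2.1), "optimal")
  expect_equal(classify_regime(4.4), "probability_summation")
  expect_equal(classify_regime(9), "independence")
  expect_equal(classify_regime(Inf), "independence")
})

test_that("noisy groups with true k in {1,2,4} are classified correctly", {
  regimes <- c("linear", "optimal", "probability_summation")
  for (j in 1:3) {
    k_true <- c(1, 2, 4)[j]
    hits <- vapply(1:200, function(s) {
      set.seed(j * 1000 + s)
      pts <- do.call(rbind, lapply(1:10, function(i) {
        T_a <- 0.27 * exp(rnorm(1, 0, 0.05))
        T_m <- 0.21 * exp(rnorm(1, 0, 0.05))
        T_am <- predict_combined_threshold(c(T_a, T_m), k_true) *
          exp(rnorm(1, 0, 0.05))
        data.frame(T_a = T_a, T_m = T_m, T_am = T_am)
      }))
      fit_pooling(pts, strict = FALSE)$regime == regimes[j]
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  }
})
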