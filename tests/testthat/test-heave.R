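test_that("heave integration matches the closed-form step response", {
  for (Zw in c(-0.1, -0.5)) {
    p <- heave_params(Zw = Zw)
    Xc <- 0.5
    tr <- simulate_heave(p, rep(Xc, 1501))
    w_exact <- (-p$Z0 / Zw) * Xc * (1 - exp(Zw * tr$t))
    rel <- abs(tr$w[-1] - w_exact[-1]) / abs(w_exact[-1])
    expect_lt(max(rel), 1e-6)
    # height is the integral of w
    h_exact <- (-p$Z0 / Zw) * Xc * (tr$t - (1 - exp(Zw * tr$t)) / (-Zw))
    expect_equal(tr$height, h_exact, tolerance = 1e-6)
  }
})

test_that("steady state and time constant follow Z0 and Zw", {
  p <- heave_params(Zw = -0.5)
  tr <- simulate_heave(p, rep(0.5, 6001))
  expect_equal(tail(tr$w, 1), (-4.8 / -0.5) * 0.5, tolerance = 1e-4)
  # 63.2% of steady state at t = 1/|Zw|
  w_ss <- (-p$Z0 / p$Zw) * 0.5
  expect_equal(tr$w[which.min(abs(tr$t - 2))], w_ss * (1 - exp(-1)),
               tolerance = 1e-6)
  p_hard <- heave_params(Zw = -0.1)
  tr_h <- simulate_heave(p_hard, rep(0.5, 6001))
  w_ss_h <- (-p_hard$Z0 / p_hard$Zw) * 0.5
  expect_equal(tr_h$w[which.min(abs(tr_h$t - 10))], w_ss_h * (1 - exp(-1)),
               tolerance = 1e-6)
})

test_that("the model is linear and bounded, and rest stays at rest", {
  p <- heave_params(Zw = -0.3)
  tr0 <- simulate_heave(p, rep(0, 500))
  expect_true(all(tr0$w == 0) && all(tr0$height == 0))
  set.seed(8)
  Xc <- as.numeric(stats::filter(rnorm(800), rep(0.2, 5), sides = 1))
  Xc[is.na(Xc)] <- 0
  t1 <- simulate_heave(p, Xc)
  t2 <- simulate_heave(p, 2 * Xc)
  expect_equal(t2$w, 2 * t1$w, tolerance = 1e-10)
  expect_equal(t2$height, 2 * t1$height, tolerance = 1e-10)
  expect_lte(max(abs(t1$w)), (-p$Z0 / p$Zw) * max(abs(Xc)) + 1e-9)
})

test_that("invalid dynamics or sampling are rejected", {
  expect_error(heave_params(Zw = 0.1), "negative")
  expect_error(heave_params(Zw = 0), "negative")
  p <- heave_params()
  expect_error(simulate_heave(p, data.frame(t = c(0, 0.01, 0.05),
                                            Xc = c(0, 0, 0))),
               "uniformly sampled|resample")
})

test_that("audio channel spans 3 dB over the collective range", {
  p <- heave_params()
  tr <- simulate_heave(p, seq(-1.5, 1.5, length.out = 501),
                       t = seq(0, 5, by = 0.01))
  tr <- cue_channels(tr)
  expect_equal(max(tr$audio_db) - min(tr$audio_db), 3, tolerance = 1e-9)
  expect_equal(range(tr$audio_db), c(86, 89), tolerance = 1e-9)
  # static mode pins the level at the base
  trs <- cue_channels(tr, audio_mode = "static")
  expect_true(all(trs$audio_db == 87.5))
  # substitute differs from variable only by the carrier label
  trx <- cue_channels(tr, audio_mode = "substitute")
  expect_equal(trx$audio_db, tr$audio_db)
  expect_equal(attr(trx, "audio_carrier"), "saxophone")
  expect_equal(attr(tr, "audio_carrier"), "turbine")
})

test_that("peak platform acceleration follows the 0.04 g/Xc calibration", {
  p <- heave_params()
  levels <- seq(0.1, 0.5, 0.1)
  peaks <- vapply(levels, function(l) {
    tr <- cue_channels(simulate_heave(p, step_control(l)))
    max(abs(tr$platform_accel_g))
  }, numeric(1))
  slope <- unname(coef(lm(peaks ~ levels))[2])
  expect_equal(slope, 0.04, tolerance = 0.01)
})

test_that("the motion channel lags the control input by 80 ms", {
  p <- heave_params()
  tr <- cue_channels(simulate_heave(p, step_control(0.3)))
  expect_equal(motion_channel_lag(tr), 0.080, tolerance = p$dt / 2)
  # cross-correlation oracle: lag of max correlation between the
  # undelayed and delayed acceleration signals
  raw <- (0.04 / p$Z0) * tr$accel
  cc <- sapply(0:20, function(s)
    cor(raw[1:(length(raw) - s)], tr$platform_accel_g[(s + 1):length(raw)]))
  expect_equal((which.max(cc) - 1) * p$dt, 0.080, tolerance = 1e-9)
  # non-multiple delays shift to the nearest sample with a warning
  expect_warning(
    cue_channels(simulate_heave(p, step_control(0.3)),
                 cue_params(motion_delay = 0.083)),
    "nearest")
})

test_that("target paths are seeded sums of six sinusoids", {
  pa <- target_path(duration = 30, dt = 0.05, seed = 9)
  pb <- target_path(duration = 30, dt = 0.05, seed = 9)
  expect_identical(pa, pb)
  comp <- attr(pa, "components")
  expect_equal(nrow(comp), 6L)
  expect_true(all(comp$frequency >= 0.2 & comp$frequency <= 0.5))
  expect_lte(max(abs(pa$target)), sum(comp$amplitude))
  # explicit single component is an exact sinusoid
  p1 <- target_path(duration = 40, dt = 0.01, n_components = 1,
                    frequencies = 0.2, amplitudes = 1, phases = 0)
  expect_equal(p1$target[which.min(abs(p1$t - pi / 0.4))], 1, tolerance = 1e-4)
  # all-zero amplitudes give a flat path
  p0 <- target_path(duration = 10, dt = 0.1, n_components = 2,
                    frequencies = c(0.2, 0.3), amplitudes = c(0, 0),
                    phases = c(0, 0))
  expect_true(all(p0$target == 0))
})

test_that("an ideal inverse pilot flies the path almost perfectly", {
  path <- target_path(duration = 40, dt = 0.01, seed = 21)
  run <- fly_tracking_run(heave_params(Zw = -0.5), path,
                          controller_spec("direct_inverse"))
  expect_lt(run$median_abs_error, 0.02)
})

test_that("difficult dynamics and missing motion cues degrade tracking", {
  dt <- 0.02
  errs <- sapply(1:3, function(sd) {
    path <- target_path(duration = 60, dt = dt, seed = sd)
    easy <- heave_params(Zw = -0.5, dt = dt)
    hard <- heave_params(Zw = -0.1, dt = dt)
    c(easy = fly_tracking_run(easy, path, seed = sd)$median_abs_error,
      hard = fly_tracking_run(hard, path, seed = sd)$median_abs_error,
      hard_nomo = fly_tracking_run(hard, path, motion_on = FALSE,
                                   seed = sd)$median_abs_error)
  })
  expect_lt(mean(errs["easy", ]), mean(errs["hard", ]))
  # motion feedback helps, run by run, where stability is at stake
  expect_true(all(errs["hard", ] <= errs["hard_nomo", ]))
})

test_that("a runaway controller raises a divergence error", {
  dt <- 0.02
  path <- target_path(duration = 30, dt = dt, seed = 2)
  wild <- controller_spec(kp = 40, kd = 0, delay = 1.0)
  # wide collective travel: the instability is not masked by saturation
  expect_error(fly_tracking_run(heave_params(Zw = -0.1, dt = dt), path, wild,
                                cues = cue_params(collective_range = 1e6),
                                diverge_limit = 100),
               "diverged")
})
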