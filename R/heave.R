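#' Heave flight-dynamics parameters
#'
#' Parameters of the single-axis (up/down) heave model
#' \deqn{\dot w = Z_w w + Z_0 X_c, \qquad \dot h = w,}
#' where `Xc` is the collective control input, `w` the vertical velocity
#' and `h` the altitude. The input gain `Z0 = 4.8` is held constant; the
#' damping `Zw` sets the handling quality: `-0.1` gives sluggish,
#' difficult-to-control dynamics (time constant 10 s), `-0.5` the "easy"
#' condition (time constant 2 s).
#'
#' @param Z0 input gain (acceleration per unit `Xc`), default 4.8.
#' @param Zw damping coefficient (1/s), must be negative; default -0.1.
#' @param dt integration step (s), default 0.01.
#' @return an object of class `heave_params`.
#' @export
heave_params <- function(Z0 = 4.8, Zw = -0.1, dt = 0.01) {
  check_param(Z0, "Z0", positive = TRUE)
  check_param(Zw, "Zw")
  check_param(dt, "dt", positive = TRUE)
  if (Zw >= 0)
    stop("'Zw' must be negative (damped, stable heave dynamics)", call. = FALSE)
  structure(list(Z0 = Z0, Zw = Zw, dt = dt), class = "heave_params")
}

#' Cue-channel calibration parameters
#'
#' Calibration of the two motion-cue channels derived from the heave
#' model state:
#' * the turbine audio level varies linearly with the control input,
#'   spanning `audio_range_db` (default 3 dB, i.e. 86-89 dB(A)) over the
#'   full collective travel around a base level of 87.5 dB(A);
#' * the motion-platform channel reproduces the model acceleration,
#'   scaled so that a unit step of `Xc` gives a peak of `motion_gain`
#'   (default 0.04 g per unit `Xc`) and delayed by `motion_delay`
#'   (default 80 ms), optionally washed out by a first-order high-pass.
#'
#' @param audio_range_db total audio-level excursion over the full
#'   collective range (dB).
#' @param audio_base_db audio level at mid-travel (dB(A)).
#' @param collective_range full collective travel (inches); default 3
#'   (i.e. +-1.5 in about centre).
#' @param motion_gain peak platform acceleration per unit `Xc` (g).
#' @param motion_delay motion-channel latency (s).
#' @param washout_tc time constant of the optional high-pass washout
#'   stub (s); 0 disables it.
#' @return an object of class `cue_params`.
#' @export
cue_params <- function(audio_range_db = 3, audio_base_db = 87.5,
                       collective_range = 3, motion_gain = 0.04,
                       motion_delay = 0.080, washout_tc = 0) {
  check_param(audio_range_db, "audio_range_db", positive = TRUE)
  check_param(audio_base_db, "audio_base_db")
  check_param(collective_range, "collective_range", positive = TRUE)
  check_param(motion_gain, "motion_gain", positive = TRUE)
  check_param(motion_delay, "motion_delay")
  check_param(washout_tc, "washout_tc")
  if (motion_delay < 0 || washout_tc < 0)
    stop("'motion_delay' and 'washout_tc' must be >= 0", call. = FALSE)
  structure(list(audio_range_db = audio_range_db,
                 audio_base_db = audio_base_db,
                 collective_range = collective_range,
                 motion_gain = motion_gain,
                 motion_delay = motion_delay,
                 washout_tc = washout_tc), class = "cue_params")
}

#' Simulate the heave model for a given control-input signal
#'
#' Integrates \eqn{\dot w = Z_w w + Z_0 X_c,\ \dot h = w} with a
#' fixed-step 4th-order Runge-Kutta scheme on the control signal's
#' uniform time grid (the control input is interpolated linearly at half
#' steps). For a constant input from rest the closed-form solution is
#' \eqn{w(t) = (-Z_0/Z_w) X_c (1 - e^{Z_w t})}: steady-state velocity
#' `-Z0/Zw * Xc`, time constant `1/|Zw|`.
#'
#' @param params a [heave_params()].
#' @param Xc control-input samples, either a numeric vector sampled at
#'   `params$dt` or a data frame with columns `t` and `Xc`.
#' @param t optional time vector matching `Xc`; must be uniform with step
#'   `params$dt`.
#' @param w0,h0 initial vertical velocity and height.
#' @return a data frame of class `heave_trace` with columns `t`, `Xc`,
#'   `accel` (`Zw*w + Z0*Xc`), `w`, `height`; the parameters are kept in
#'   attribute `"params"`.
#' @examples
#' p <- heave_params(Zw = -0.5)
#' tr <- simulate_heave(p, rep(0.5, 2001))
#' tail(tr$w, 1)  # -> steady state -Z0/Zw * 0.5 = 4.8
#' @export
simulate_heave <- function(params, Xc, t = NULL, w0 = 0, h0 = 0) {
  stopifnot(inherits(params, "heave_params"))
  if (is.data.frame(Xc)) { t <- Xc$t; Xc <- Xc$Xc }
  if (!is.numeric(Xc) || length(Xc) < 2L || any(!is.finite(Xc)))
    stop("'Xc' must be a finite numeric signal with >= 2 samples",
         call. = FALSE)
  n <- length(Xc)
  if (is.null(t)) t <- (seq_len(n) - 1L) * params$dt
  d <- diff(t)
  if (any(abs(d - params$dt) > 1e-8 * max(params$dt, 1)))
    stop("control signal must be uniformly sampled at dt = ", params$dt,
         "; resample before simulating", call. = FALSE)

  Zw <- params$Zw; Z0 <- params$Z0; dt <- params$dt
  w <- numeric(n); h <- numeric(n)
  w[1] <- w0; h[1] <- h0
  for (i in seq_len(n - 1L)) {
    u0 <- Xc[i]; u1 <- Xc[i + 1L]; um <- (u0 + u1) / 2
    # RK4 on state (w, h)
    k1w <- Zw * w[i] + Z0 * u0
    k1h <- w[i]
    k2w <- Zw * (w[i] + dt / 2 * k1w) + Z0 * um
    k2h <- w[i] + dt / 2 * k1w
    k3w <- Zw * (w[i] + dt / 2 * k2w) + Z0 * um
    k3h <- w[i] + dt / 2 * k2w
    k4w <- Zw * (w[i] + dt * k3w) + Z0 * u1
    k4h <- w[i] + dt * k3w
    w[i + 1L] <- w[i] + dt / 6 * (k1w + 2 * k2w + 2 * k3w + k4w)
    h[i + 1L] <- h[i] + dt / 6 * (k1h + 2 * k2h + 2 * k3h + k4h)
  }
  out <- data.frame(t = t, Xc = Xc, accel = Zw * w + Z0 * Xc,
                    w = w, height = h)
  attr(out, "params") <- params
  class(out) <- c("heave_trace", "data.frame")
  out
}

#' Derive the auditory and kinematic cue channels from a heave trace
#'
#' Fills in the two cue channels:
#' * `audio_db` — turbine level, `audio_base_db` plus a linear term in
#'   `Xc` spanning `audio_range_db` over the full collective range
#'   (`variable` and `substitute` modes; `substitute` differs only in the
#'   carrier label attribute), or constant at the base level (`static`);
#' * `platform_accel_g` — the model acceleration scaled by
#'   `motion_gain / Z0` (so a unit `Xc` step peaks at `motion_gain` g),
#'   shifted by `motion_delay` (nearest sample, with a warning when the
#'   delay is not a multiple of `dt`) and optionally high-pass washed out.
#'
#' @param trace a [simulate_heave()] result.
#' @param cues a [cue_params()].
#' @param audio_mode `"variable"`, `"static"` or `"substitute"`.
#' @return the trace with columns `audio_db` and `platform_accel_g`
#'   added; the audio carrier is recorded in attribute `"audio_carrier"`
#'   (`"turbine"` or `"saxophone"`).
#' @export
cue_channels <- function(trace, cues = cue_params(),
                         audio_mode = c("variable", "static", "substitute")) {
  stopifnot(inherits(trace, "heave_trace"), inherits(cues, "cue_params"))
  audio_mode <- match.arg(audio_mode)
  params <- attr(trace, "params")

  slope <- cues$audio_range_db / cues$collective_range  # dB per inch
  trace$audio_db <- if (audio_mode == "static")
    rep(cues$audio_base_db, nrow(trace))
  else
    cues$audio_base_db + slope * trace$Xc

  shift_exact <- cues$motion_delay / params$dt
  shift <- as.integer(round(shift_exact))
  if (abs(shift_exact - shift) > 1e-8)
    warning("motion_delay is not a multiple of dt; shifting by the nearest ",
            "sample (", shift, " samples = ", shift * params$dt, " s)")
  pg <- (cues$motion_gain / params$Z0) * trace$accel
  if (cues$washout_tc > 0) {
    a <- cues$washout_tc / (cues$washout_tc + params$dt)
    y <- numeric(length(pg)); y[1] <- pg[1]
    for (i in 2:length(pg)) y[i] <- a * (y[i - 1] + pg[i] - pg[i - 1])
    pg <- y
  }
  trace$platform_accel_g <- if (shift > 0)
    c(numeric(shift), pg[seq_len(nrow(trace) - shift)])
  else pg
  attr(trace, "cues") <- cues
  attr(trace, "audio_carrier") <-
    switch(audio_mode, substitute = "saxophone", "turbine")
  trace
}

#' Sum-of-sinusoids target path
#'
#' Target altitude defined as the sum of `n_components` sinusoids with
#' frequencies in `freq_range` (default six components, 0.2-0.5 rad/s),
#' each with its own amplitude and phase. Complex enough that a pilot
#' cannot memorise it, yet identical across calls with the same seed and
#' parameters. Components not supplied are seeded draws: frequencies
#' evenly spaced over the range, amplitudes uniform on [0.5, 1.5] ft,
#' phases uniform on [0, 2*pi).
#'
#' @param duration path length (s).
#' @param dt sample step (s).
#' @param n_components number of sinusoids.
#' @param freq_range frequency range (rad/s).
#' @param frequencies,amplitudes,phases optional explicit per-component
#'   values (recycled checks applied).
#' @param seed optional integer seed for the drawn components.
#' @return data frame with columns `t` and `target` (ft); components kept
#'   in attribute `"components"`.
#' @export
target_path <- function(duration = 120, dt = 0.01, n_components = 6,
                        freq_range = c(0.2, 0.5), frequencies = NULL,
                        amplitudes = NULL, phases = NULL, seed = NULL) {
  check_param(duration, "duration", positive = TRUE)
  check_param(dt, "dt", positive = TRUE)
  with_seed(seed, {
    if (is.null(frequencies))
      frequencies <- seq(freq_range[1], freq_range[2],
                         length.out = n_components)
    if (any(frequencies < freq_range[1] - 1e-12) ||
        any(frequencies > freq_range[2] + 1e-12))
      stop("'frequencies' must lie within freq_range", call. = FALSE)
    if (is.null(amplitudes)) amplitudes <- stats::runif(n_components, 0.5, 1.5)
    if (is.null(phases)) phases <- stats::runif(n_components, 0, 2 * pi)
    stopifnot(length(frequencies) == n_components,
              length(amplitudes) == n_components,
              length(phases) == n_components)
    t <- seq(0, duration, by = dt)
    h <- rowSums(vapply(seq_len(n_components), function(i)
      amplitudes[i] * sin(frequencies[i] * t + phases[i]), numeric(length(t))))
    out <- data.frame(t = t, target = h)
    attr(out, "components") <- data.frame(frequency = frequencies,
                                          amplitude = amplitudes,
                                          phase = phases)
    out
  })
}

#' Ramp-and-hold control input
#'
#' The step-like control inputs used to probe the cue channels: zero
#' until `onset`, then a linear ramp to `level` over `rise` seconds, then
#' hold.
#'
#' @param level plateau control input (collective inches; signed).
#' @param duration total signal length (s).
#' @param dt sample step (s).
#' @param onset ramp start time (s).
#' @param rise ramp duration (s).
#' @return data frame with columns `t` and `Xc`.
#' @export
step_control <- function(level, duration = 10, dt = 0.01, onset = 1,
                         rise = 0.1) {
  t <- seq(0, duration, by = dt)
  Xc <- pmin(pmax((t - onset) / max(rise, dt), 0), 1) * level
  data.frame(t = t, Xc = Xc)
}

#' Measured onset lag of the motion-cue channel
#'
#' First time at which `platform_accel_g` departs from baseline, minus
#' the first time the control input departs from zero.
#'
#' @param trace a [cue_channels()] result.
#' @param tol departure tolerance.
#' @return lag in seconds.
#' @export
motion_channel_lag <- function(trace, tol = 1e-9) {
  i_x <- which(abs(trace$Xc) > tol)[1]
  i_p <- which(abs(trace$platform_accel_g) > tol)[1]
  if (is.na(i_x) || is.na(i_p))
    stop("no onset found in Xc or platform channel", call. = FALSE)
  trace$t[i_p] - trace$t[i_x]
}
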