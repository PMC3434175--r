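#' Synthetic pilot (controller) specification
#'
#' A simple human-like tracking controller for the heave model. The
#' pilot observes the height error through a delayed, noisy visual
#' channel and adds a pursuit term — the target rate minus an estimate
#' of the own vertical velocity — whose quality depends on the
#' available cues:
#'
#' * with the motion platform on, velocity feedback comes from the
#'   vestibular/kinematic channel: the true velocity at the short
#'   motion-channel latency (80 ms by default) plus low-amplitude noise
#'   (`sigma_vel`);
#' * with the platform off, velocity must be inferred by differencing
#'   the delayed noisy visual height over `diff_window` seconds — a
#'   noisier, more sluggish estimate that destabilises the weakly
#'   damped difficult dynamics in particular;
#' * an informative turbine sound can sharpen the velocity estimate, but
#'   only in proportion to `audio_weight` — an untrained pilot
#'   (`audio_weight = 0`, the default) ignores it, matching the
#'   observation that audio cues help only after training;
#' * the auditory error beep is available as a flag but has no effect at
#'   the default `beep_gain = 0`.
#'
#' `kind = "direct_inverse"` is an idealised pilot that inverts the plant
#' exactly from the target derivatives, with no delay or noise; it flies
#' the path essentially perfectly and anchors the zero of the error
#' metric.
#'
#' @param kind `"proportional_derivative_delay"` (default),
#'   `"proportional_delay"` (no velocity damping term) or
#'   `"direct_inverse"`.
#' @param kp proportional gain on the height error (Xc per ft).
#' @param kd gain on the velocity estimate (Xc per ft/s).
#' @param delay visuomotor delay (s).
#' @param sigma_height visual height-measurement noise SD (ft).
#' @param sigma_vel kinematic velocity-feedback noise SD (ft/s).
#' @param diff_window differencing window for the visual velocity
#'   estimate (s).
#' @param audio_weight 0..1, fractional reduction of velocity-estimate
#'   noise attributable to an informative (and attended) turbine cue.
#' @param beep_gain 0..1, fractional reduction of height-error noise
#'   attributable to the error beep.
#' @return an object of class `controller_spec`.
#' @export
controller_spec <- function(kind = c("proportional_derivative_delay",
                                     "proportional_delay", "direct_inverse"),
                            kp = 0.6, kd = 0.1, delay = 0.2,
                            sigma_height = 0.1, sigma_vel = 0.05,
                            diff_window = 0.15, audio_weight = 0,
                            beep_gain = 0) {
  kind <- match.arg(kind)
  check_param(kp, "kp"); check_param(kd, "kd"); check_param(delay, "delay")
  check_param(sigma_height, "sigma_height"); check_param(sigma_vel, "sigma_vel")
  if (audio_weight < 0 || audio_weight > 1 || beep_gain < 0 || beep_gain > 1)
    stop("'audio_weight' and 'beep_gain' must lie in [0, 1]", call. = FALSE)
  structure(list(kind = kind, kp = kp, kd = kd, delay = delay,
                 sigma_height = sigma_height, sigma_vel = sigma_vel,
                 diff_window = diff_window, audio_weight = audio_weight,
                 beep_gain = beep_gain), class = "controller_spec")
}

#' Fly a target-tracking run with a synthetic pilot
#'
#' Closed-loop simulation of the tracking task: at every integration
#' step the controller turns its (delayed, noisy) state estimate into a
#' collective input, which is held over the step while the heave model
#' advances one RK4 step. Performance is scored as the median absolute
#' height error in ft. Deterministic given `seed`.
#'
#' @param params a [heave_params()]; `Zw = -0.5` is the easy dynamics,
#'   `-0.1` the difficult one.
#' @param path a [target_path()] data frame sampled at `params$dt`.
#' @param controller a [controller_spec()].
#' @param cues a [cue_params()] (bounds the collective travel).
#' @param motion_on,turbine_on,error_beep_on cue availability flags; see
#'   [controller_spec()] for how they modulate the state-estimate noise.
#' @param seed optional integer seed.
#' @param subject_id identifier attached to the run.
#' @param factors optional named list of design labels (e.g.
#'   `list(e = 0, t = 1, m = 1, d = 0)`) carried into the result.
#' @param diverge_limit abort threshold on `|error|` (ft); exceeding it
#'   raises a divergence error with the offending time.
#' @return an object of class `tracking_run`: list with `trace`
#'   (`t`, `target`, `flown`, `Xc`), `median_abs_error`, `subject_id`,
#'   `factors`, `controller`, `params`.
#' @export
fly_tracking_run <- function(params, path, controller = controller_spec(),
                             cues = cue_params(), motion_on = TRUE,
                             turbine_on = TRUE, error_beep_on = FALSE,
                             seed = NULL, subject_id = "P1", factors = NULL,
                             diverge_limit = 1e4) {
  stopifnot(inherits(params, "heave_params"),
            inherits(controller, "controller_spec"),
            inherits(cues, "cue_params"))
  t <- path$t; target <- path$target
  n <- length(t)
  if (n < 3L || any(abs(diff(t) - params$dt) > 1e-8))
    stop("'path' must be sampled uniformly at params$dt", call. = FALSE)
  dt <- params$dt; Zw <- params$Zw; Z0 <- params$Z0
  half_travel <- cues$collective_range / 2

  if (controller$kind == "direct_inverse") {
    # exact plant inversion from target derivatives; no noise, no delay
    dh <- c(diff(target), NA) / dt
    dh[n] <- dh[n - 1]
    ddh <- c(NA, diff(target, differences = 2), NA) / dt^2
    ddh[1] <- ddh[2]; ddh[n] <- ddh[n - 1]
    Xc <- (ddh - Zw * dh) / Z0
    tr <- simulate_heave(params, Xc, t = t, w0 = dh[1], h0 = target[1])
    flown <- tr$height
    run_Xc <- Xc
  } else {
    nd <- max(1L, as.integer(round(controller$delay / dt)))
    nd_m <- max(1L, as.integer(round(cues$motion_delay / dt)))
    kdiff <- max(1L, as.integer(round(controller$diff_window / dt)))
    s_h <- controller$sigma_height *
      (1 - controller$beep_gain * as.numeric(error_beep_on))
    s_v <- controller$sigma_vel
    audio_factor <- 1 - controller$audio_weight *
      as.numeric(turbine_on)
    use_kd <- controller$kind == "proportional_derivative_delay"

    flown <- numeric(n); run_Xc <- numeric(n)
    w <- 0; h <- target[1]
    flown[1] <- h
    eps_h <- with_seed(seed, list(h = stats::rnorm(n, 0, 1),
                                  v = stats::rnorm(n, 0, 1)))
    h_meas <- numeric(n)  # noisy delayed visual height record
    w_hist <- numeric(n)
    w_hist[1] <- w
    for (i in seq_len(n - 1L)) {
      j <- max(1L, i - nd)
      h_meas[i] <- flown[j] + s_h * eps_h$h[i]
      e_meas <- target[j] - h_meas[i]
      # pursuit term: rate of the target minus own velocity, both taken at
      # the latency of the velocity source in use (kinematic feedback is
      # faster than the visual differencing estimate)
      jv <- if (motion_on) max(1L, i - nd_m) else j
      jp <- max(1L, jv - kdiff)
      vt_est <- if (jv > jp) (target[jv] - target[jp]) / ((jv - jp) * dt) else 0
      w_est <- if (!use_kd) 0
      else if (motion_on)
        w_hist[jv] + s_v * audio_factor * eps_h$v[i]
      else if (i > kdiff + 1L)
        (h_meas[i] - h_meas[i - kdiff]) / (kdiff * dt) * audio_factor +
          (1 - audio_factor) * w_hist[j]
      else 0
      u <- controller$kp * e_meas +
        controller$kd * (vt_est - w_est) * as.numeric(use_kd)
      u <- min(max(u, -half_travel), half_travel)
      run_Xc[i] <- u
      # one RK4 step with Xc held constant (zero-order hold)
      k1w <- Zw * w + Z0 * u;            k1h <- w
      k2w <- Zw * (w + dt / 2 * k1w) + Z0 * u; k2h <- w + dt / 2 * k1w
      k3w <- Zw * (w + dt / 2 * k2w) + Z0 * u; k3h <- w + dt / 2 * k2w
      k4w <- Zw * (w + dt * k3w) + Z0 * u;     k4h <- w + dt * k3w
      w <- w + dt / 6 * (k1w + 2 * k2w + 2 * k3w + k4w)
      h <- h + dt / 6 * (k1h + 2 * k2h + 2 * k3h + k4h)
      flown[i + 1L] <- h
      w_hist[i + 1L] <- w
      if (!is.finite(h) || abs(h - target[i + 1L]) > diverge_limit)
        stop("controller diverged at t = ", round(t[i + 1L], 2),
             " s (|error| > ", diverge_limit, " ft); reduce gains or delay",
             call. = FALSE)
    }
    run_Xc[n] <- run_Xc[n - 1L]
  }

  structure(list(
    trace = data.frame(t = t, target = target, flown = flown, Xc = run_Xc),
    median_abs_error = stats::median(abs(target - flown)),
    subject_id = subject_id,
    factors = factors,
    motion_on = motion_on, turbine_on = turbine_on,
    error_beep_on = error_beep_on,
    controller = controller, params = params
  ), class = "tracking_run")
}

#' @export
print.tracking_run <- function(x, ...) {
  cat(sprintf("tracking run [%s]: %.1f s, median |error| = %.3f ft\n",
              x$subject_id, max(x$trace$t), x$median_abs_error))
  if (!is.null(x$factors))
    cat("  factors:", paste(names(x$factors), unlist(x$factors),
                            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Simulate a factorial tracking cohort
#'
#' Flies every cell of the 2x2x2x2 within-subject design — error beep
#' (`e`), informative turbine (`t`), motion platform (`m`), difficult
#' dynamics (`d`) — for each synthetic pilot, mirroring the
#' target-tracking experiment. Pilot gains are jittered log-normally
#' across subjects; `d = 1` flies `Zw = -0.1`, `d = 0` flies
#' `Zw = -0.5`. Deterministic given `seed`.
#'
#' @param n_subjects number of synthetic pilots.
#' @param duration run length (s).
#' @param dt integration step (s).
#' @param base_controller base [controller_spec()] jittered per subject.
#' @param audio_weight turbine-cue utilisation (0 = untrained pilots).
#' @param gain_jitter SD of the log-normal gain spread across subjects.
#' @param seed integer seed.
#' @return data frame with columns `subject_id`, `e`, `t`, `m`, `d`
#'   (0/1) and `median_abs_error` (ft), one row per subject x cell.
#' @export
simulate_factorial_runs <- function(n_subjects = 10, duration = 60, dt = 0.02,
                                    base_controller = controller_spec(),
                                    audio_weight = 0, gain_jitter = 0.1,
                                    seed = 1) {
  cells <- expand.grid(e = 0:1, t = 0:1, m = 0:1, d = 0:1)
  with_seed(seed, {
    res <- vector("list", n_subjects * nrow(cells))
    idx <- 1L
    for (s in seq_len(n_subjects)) {
      jit <- exp(stats::rnorm(2, 0, gain_jitter))
      ctrl <- controller_spec(
        kind = base_controller$kind,
        kp = base_controller$kp * jit[1], kd = base_controller$kd * jit[2],
        delay = base_controller$delay,
        sigma_height = base_controller$sigma_height,
        sigma_vel = base_controller$sigma_vel,
        diff_window = base_controller$diff_window,
        audio_weight = audio_weight,
        beep_gain = base_controller$beep_gain)
      path <- target_path(duration, dt,
                          seed = sample.int(.Machine$integer.max / 2, 1))
      for (c_i in seq_len(nrow(cells))) {
        cell <- cells[c_i, ]
        pars <- heave_params(Zw = if (cell$d == 1) -0.1 else -0.5, dt = dt)
        run <- fly_tracking_run(
          pars, path, ctrl,
          motion_on = cell$m == 1, turbine_on = cell$t == 1,
          error_beep_on = cell$e == 1,
          seed = sample.int(.Machine$integer.max / 2, 1),
          subject_id = paste0("P", s))
        res[[idx]] <- data.frame(subject_id = paste0("P", s),
                                 e = cell$e, t = cell$t, m = cell$m,
                                 d = cell$d,
                                 median_abs_error = run$median_abs_error)
        idx <- idx + 1L
      }
    }
    do.call(rbind, res)
  })
}
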