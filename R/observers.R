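#' Specify a mechanistic forced-choice observer
#'
#' Defines a synthetic observer for the up/down motion-categorisation
#' task. Each kind implements a decision mechanism that realises one of
#' the canonical cue-integration regimes, so the whole analysis chain
#' (simulate trials, fit psychometric thresholds, fit the pooling
#' exponent) can be exercised end to end:
#'
#' * `optimal_gaussian` — each cue yields a noisy Gaussian estimate of
#'   the signed input; in the bimodal condition the two are combined by
#'   inverse-variance (reliability) weighting before one sign decision.
#'   Realises `k = 2`.
#' * `linear_late_noise` — channel outputs `g_i x` (gains `g_i = 1/sigma_i`)
#'   are summed into one decision variable carrying a single late noise
#'   source of unit standard deviation. Realises `k = 1`.
#' * `probability_summation` — each channel independently "detects" the
#'   stimulus with Weibull probability `1 - exp(-(|x|/s_i)^m_channel)`
#'   and, when it detects, reports the true sign; the observer answers
#'   with a detecting channel's report (audio wins ties — immaterial for
#'   correctness) and guesses otherwise. Realises `k = m_channel`.
#' * `single_channel` — one cue only; the bimodal condition is a spec
#'   mismatch error.
#'
#' The default sigmas are calibrated so the unimodal 81%-correct
#' thresholds land at 0.27 (audio) and 0.21 (motion) control-input units,
#' the magnitudes reported for a representative subject; for the
#' probability-summation kind the sigmas are mapped to channel Weibull
#' scales that preserve those same 81% thresholds.
#'
#' @param kind observer mechanism (see above).
#' @param sigma_a audio-channel internal noise SD (level units).
#' @param sigma_m motion-channel internal noise SD (level units).
#' @param m_channel channel Weibull slope for `probability_summation`.
#' @param subject_id identifier carried into simulated trial tables.
#' @return an object of class `observer_spec`.
#' @examples
#' observer_spec("optimal_gaussian")
#' observer_threshold(observer_spec("optimal_gaussian"), "both")  # ~0.166
#' @export
observer_spec <- function(kind = c("optimal_gaussian", "linear_late_noise",
                                   "probability_summation", "single_channel"),
                          sigma_a = 0.27 / stats::qnorm(0.81),
                          sigma_m = 0.21 / stats::qnorm(0.81),
                          m_channel = 4,
                          subject_id = "S1") {
  kind <- match.arg(kind)
  check_param(sigma_a, "sigma_a", positive = TRUE)
  check_param(sigma_m, "sigma_m", positive = TRUE)
  check_param(m_channel, "m_channel", positive = TRUE)
  structure(list(kind = kind, sigma_a = sigma_a, sigma_m = sigma_m,
                 m_channel = m_channel, subject_id = subject_id),
            class = "observer_spec")
}

#' @export
print.observer_spec <- function(x, ...) {
  cat(sprintf("observer '%s' [%s]: sigma_a = %.4g, sigma_m = %.4g",
              x$subject_id, x$kind, x$sigma_a, x$sigma_m))
  if (x$kind == "probability_summation")
    cat(sprintf(", m_channel = %g", x$m_channel))
  cat("\n")
  invisible(x)
}

#' Design of a forced-choice session
#'
#' @param levels signed control-input levels. Default the ten signed
#'   levels `+-{0.1, ..., 0.5}`. A level of exactly 0 is allowed and is
#'   treated as a catch trial: no signal is presented and correctness is
#'   scored against a randomly designated nominal direction, so long-run
#'   accuracy is 50%.
#' @param trials_per_level repetitions of each signed level per condition.
#' @param conditions cue conditions to run, subset of
#'   `c("audio", "motion", "both")`.
#' @return an object of class `session_design`.
#' @export
session_design <- function(levels = c(-(5:1), 1:5) / 10,
                           trials_per_level = 20,
                           conditions = c("audio", "motion", "both")) {
  if (!is.numeric(levels) || length(levels) < 1L || any(!is.finite(levels)))
    stop("'levels' must be finite numbers", call. = FALSE)
  if (!is.numeric(trials_per_level) || trials_per_level < 1)
    stop("'trials_per_level' must be >= 1", call. = FALSE)
  conditions <- match.arg(conditions, several.ok = TRUE)
  structure(list(levels = levels, trials_per_level = as.integer(trials_per_level),
                 conditions = conditions), class = "session_design")
}

# channel Weibull scale for the probability-summation kind: chosen so the
# unimodal 81% threshold equals sigma * qnorm(0.81), as for Gaussian kinds
ps_channel_scale <- function(sigma, m_channel) {
  sigma * stats::qnorm(0.81) / (-log((1 - 0.81) / 0.5))^(1 / m_channel)
}

#' Simulate a forced-choice categorisation session
#'
#' Draws one response per (condition, level, repetition) from the
#' observer's decision mechanism (see [observer_spec()]). Deterministic
#' given `seed`: trials are generated in a fixed order (condition, then
#' level, then repetition).
#'
#' @param observer an [observer_spec()].
#' @param design a [session_design()].
#' @param seed optional integer seed.
#' @return data frame of trial records with columns `subject_id`,
#'   `condition`, `level`, `response` (`"up"`/`"down"`), `correct`.
#' @export
simulate_session <- function(observer, design = session_design(), seed = NULL) {
  stopifnot(inherits(observer, "observer_spec"),
            inherits(design, "session_design"))
  if (observer$kind == "single_channel" && "both" %in% design$conditions)
    stop("spec mismatch: a single_channel observer cannot run the 'both' ",
         "condition", call. = FALSE)
  with_seed(seed, {
    out <- lapply(design$conditions, function(cond)
      simulate_condition(observer, cond, design$levels, design$trials_per_level))
    do.call(rbind, out)
  })
}

simulate_condition <- function(obs, cond, levels, tpl) {
  x <- rep(levels, each = tpl)
  n <- length(x)
  resp_sign <- switch(obs$kind,
    single_channel = ,
    optimal_gaussian = {
      if (cond == "both") {
        wa <- 1 / obs$sigma_a^2; wm <- 1 / obs$sigma_m^2
        sa <- x + stats::rnorm(n, 0, obs$sigma_a)
        sm <- x + stats::rnorm(n, 0, obs$sigma_m)
        sign_nz((wa * sa + wm * sm) / (wa + wm))
      } else {
        s <- x + stats::rnorm(n, 0, if (cond == "audio") obs$sigma_a else obs$sigma_m)
        sign_nz(s)
      }
    },
    linear_late_noise = {
      ga <- 1 / obs$sigma_a; gm <- 1 / obs$sigma_m
      g <- switch(cond, audio = ga, motion = gm, both = ga + gm)
      sign_nz(g * x + stats::rnorm(n, 0, 1))
    },
    probability_summation = {
      sa <- ps_channel_scale(obs$sigma_a, obs$m_channel)
      sm <- ps_channel_scale(obs$sigma_m, obs$m_channel)
      det_a <- if (cond %in% c("audio", "both"))
        stats::runif(n) < 1 - exp(-(abs(x) / sa)^obs$m_channel) else rep(FALSE, n)
      det_m <- if (cond %in% c("motion", "both"))
        stats::runif(n) < 1 - exp(-(abs(x) / sm)^obs$m_channel) else rep(FALSE, n)
      guess <- sample(c(-1, 1), n, replace = TRUE)
      # a detecting channel reports the true sign; audio wins ties
      ifelse(det_a | det_m, sign_nz(x), guess)
    })
  # catch trials (level 0): score against a random nominal direction
  nominal <- ifelse(x == 0, sample(c(-1, 1), n, replace = TRUE), sign(x))
  data.frame(subject_id = obs$subject_id,
             condition = cond,
             level = x,
             response = ifelse(resp_sign > 0, "up", "down"),
             correct = resp_sign == nominal)
}

# sign() that never returns 0 (measure-zero ties resolved upward)
sign_nz <- function(x) ifelse(x >= 0, 1, -1)

#' Analytic proportion correct for an observer
#'
#' Closed-form psychometric function of each observer mechanism: the
#' Gaussian kinds give `pnorm(|x|/sigma_eff)`; the probability-summation
#' kind gives the OR-rule form `1 - 0.5 * exp(-sum_i (|x|/s_i)^m)`.
#' Used as the independent oracle against which simulated correct rates
#' are checked.
#'
#' @param observer an [observer_spec()].
#' @param condition one of `"audio"`, `"motion"`, `"both"`.
#' @param x signed or absolute level(s).
#' @return probabilities of a correct categorisation.
#' @export
observer_pcorrect <- function(observer, condition = c("audio", "motion", "both"),
                              x) {
  condition <- match.arg(condition)
  a <- abs(x)
  if (observer$kind == "single_channel" && condition == "both")
    stop("spec mismatch: single_channel has no 'both' condition", call. = FALSE)
  switch(observer$kind,
    single_channel = ,
    optimal_gaussian = {
      s <- switch(condition,
        audio = observer$sigma_a,
        motion = observer$sigma_m,
        both = sqrt(1 / (1 / observer$sigma_a^2 + 1 / observer$sigma_m^2)))
      stats::pnorm(a / s)
    },
    linear_late_noise = {
      ga <- 1 / observer$sigma_a; gm <- 1 / observer$sigma_m
      g <- switch(condition, audio = ga, motion = gm, both = ga + gm)
      stats::pnorm(g * a)
    },
    probability_summation = {
      m <- observer$m_channel
      sa <- ps_channel_scale(observer$sigma_a, m)
      sm <- ps_channel_scale(observer$sigma_m, m)
      e <- switch(condition,
        audio = (a / sa)^m,
        motion = (a / sm)^m,
        both = (a / sa)^m + (a / sm)^m)
      1 - 0.5 * exp(-e)
    })
}

#' Analytic 81%-correct threshold for an observer
#'
#' Inverts [observer_pcorrect()] at probability `p`.
#'
#' @inheritParams observer_pcorrect
#' @param p probability criterion, default 0.81.
#' @return the threshold level.
#' @export
observer_threshold <- function(observer, condition = c("audio", "motion", "both"),
                               p = 0.81) {
  condition <- match.arg(condition)
  stats::uniroot(function(x) observer_pcorrect(observer, condition, x) - p,
                 c(1e-8, 100), tol = 1e-12)$root
}

#' Generate a heterogeneous cohort of observers
#'
#' Draws per-subject channel noise levels log-normally around a base
#' observer: each subject's `sigma_a` and `sigma_m` are the base values
#' multiplied by independent `exp(rnorm(0, heterogeneity))` factors.
#' Deterministic given `seed`.
#'
#' @param n_subjects number of observers.
#' @param base base [observer_spec()].
#' @param heterogeneity SD of the log-normal multiplicative spread
#'   (0 = identical subjects).
#' @param seed optional integer seed.
#' @return list of `observer_spec`s with subject ids `S1..Sn`.
#' @export
make_cohort <- function(n_subjects, base = observer_spec(),
                        heterogeneity = 0.15, seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("'n_subjects' must be >= 1", call. = FALSE)
  if (!is.numeric(heterogeneity) || heterogeneity < 0)
    stop("'heterogeneity' must be >= 0", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      fa <- exp(stats::rnorm(1, 0, heterogeneity))
      fm <- exp(stats::rnorm(1, 0, heterogeneity))
      observer_spec(base$kind, sigma_a = base$sigma_a * fa,
                    sigma_m = base$sigma_m * fm,
                    m_channel = base$m_channel,
                    subject_id = paste0("S", i))
    })
  })
}

#' Fitted threshold triple for one observer
#'
#' Runs the full experiment-1 chain for a single observer: simulate a
#' session in all three cue conditions, fit a Weibull psychometric
#' function per condition, and return the three 81% thresholds.
#'
#' @param observer an [observer_spec()].
#' @param design a [session_design()] covering `audio`, `motion`, `both`.
#' @param seed optional integer seed for the session.
#' @return one-row data frame `subject_id`, `T_a`, `T_m`, `T_am`.
#' @export
observer_threshold_triple <- function(observer, design = session_design(),
                                      seed = NULL) {
  trials <- simulate_session(observer, design, seed = seed)
  th <- vapply(c("audio", "motion", "both"), function(cond)
    fit_psychometric(trials[trials$condition == cond, ])$threshold,
    numeric(1))
  data.frame(subject_id = observer$subject_id,
             T_a = th[["audio"]], T_m = th[["motion"]], T_am = th[["both"]])
}
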