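#' Fit a Weibull psychometric function by maximum likelihood
#'
#' Fits the two free Weibull parameters (scale `x0`, shape `m`) to a table
#' of forced-choice categorisation trials for one subject and one cue
#' condition, treating each trial as an independent Bernoulli draw with
#' success probability [weibull_p()] at the trial's absolute level. The
#' asymptotes are fixed at chance (`A = 0.5`) and perfect performance
#' (`B = 1`). The reported threshold is the level at which the fitted
#' curve crosses `p_threshold` (default the 81% criterion), solved in
#' closed form by [threshold_at()].
#'
#' Trials with response `"none"` (or flagged `excluded`) are discounted
#' before fitting. By default equivalent up and down levels are pooled
#' onto their absolute magnitude, mirroring the usual practice when
#' direction-specific tests show no asymmetry; with `pool_updown = FALSE`
#' all trials must share one direction.
#'
#' The optimiser is a coarse grid over `(x0, m)` (log-spaced, covering
#' well beyond the tested level range) followed by Nelder-Mead refinement
#' on the log scale; it uses no random numbers, so fits are reproducible
#' without a seed.
#'
#' @param trials data frame with columns `level` (signed, nonzero) and
#'   either `correct` (logical) or `response` (`"up"`/`"down"`/`"none"`);
#'   typically one subject x condition slice of [simulate_session()] output
#'   or of [read_trials()].
#' @param pool_updown pool `+x` and `-x` levels onto `|x|` before fitting
#'   (default `TRUE`).
#' @param p_threshold probability criterion for the reported threshold
#'   (default 0.81).
#' @param A,B fixed asymptotes.
#' @return an object of class `psychfit`: a list with `coefficients`
#'   (`x0`, `m`), `A`, `B`, `threshold`, `p_threshold`, `loglik`,
#'   `counts` (per-level trial counts and observed proportions),
#'   `n_trials`.
#' @section Errors:
#' Fewer than two distinct absolute levels raises an insufficient-data
#' error. Data that are all correct, all incorrect, or indistinguishable
#' from chance at every level (so the likelihood is maximised only as
#' `x0` escapes the data range) raise a degenerate-fit error carrying the
#' per-level summary.
#' @examples
#' obs <- observer_spec("optimal_gaussian")
#' tr  <- simulate_session(obs, session_design(trials_per_level = 50), seed = 1)
#' fit <- fit_psychometric(tr[tr$condition == "both", ])
#' coef(fit); fit$threshold
#' @export
fit_psychometric <- function(trials, pool_updown = TRUE, p_threshold = 0.81,
                             A = 0.5, B = 1.0) {
  trials <- as.data.frame(trials)
  if (!"level" %in% names(trials))
    stop("'trials' must contain a 'level' column", call. = FALSE)
  if (!is.null(trials$excluded)) trials <- trials[!trials$excluded, , drop = FALSE]
  if (!is.null(trials$response)) trials <- trials[trials$response != "none", , drop = FALSE]
  if (is.null(trials$correct)) {
    if (is.null(trials$response))
      stop("'trials' must contain 'correct' or 'response'", call. = FALSE)
    trials$correct <- (trials$response == "up") == (trials$level > 0)
  }
  if (!pool_updown && length(unique(sign(trials$level))) > 1L)
    stop("pool_updown = FALSE requires trials from a single direction",
         call. = FALSE)
  x_abs <- abs(trials$level)
  if (any(!is.finite(x_abs)) || any(x_abs <= 0))
    stop("trial levels must be finite and nonzero", call. = FALSE)

  lev <- sort(unique(x_abs))
  n <- vapply(lev, function(l) sum(x_abs == l), integer(1))
  if (any(n == 0L)) {
    warning("dropping levels with no valid trials: ",
            paste(lev[n == 0L], collapse = ", "))
    lev <- lev[n > 0L]; n <- n[n > 0L]
  }
  k <- vapply(lev, function(l) sum(trials$correct[x_abs == l]), integer(1))
  counts <- data.frame(level = lev, n = n, correct = k, prop = k / n)

  if (length(lev) < 2L)
    stop("insufficient data: need at least 2 distinct absolute levels, got ",
         length(lev), call. = FALSE)
  if (sum(k) == sum(n) || sum(k) == 0L)
    stop(degenerate_fit_error(counts,
      "all trials correct or all incorrect; likelihood has no interior maximum"))

  nll <- function(par) {
    x0 <- exp(par[1]); m <- exp(par[2])
    p <- A + (B - A) * (1 - exp(-(lev / x0)^m))
    p <- pmin(pmax(p, A + 1e-12), B - 1e-12)
    -sum(k * log(p) + (n - k) * log1p(-p))
  }

  # coarse grid initialisation (deterministic), then Nelder-Mead on logs
  x0g <- exp(seq(log(0.1 * min(lev)), log(20 * max(lev)), length.out = 30))
  mg  <- exp(seq(log(0.3), log(12), length.out = 25))
  grid <- expand.grid(lx0 = log(x0g), lm = log(mg))
  gv <- apply(grid, 1L, nll)
  init <- as.numeric(grid[which.min(gv), ])
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
  x0 <- exp(opt$par[1]); m <- exp(opt$par[2])

  # flat fit: the curve never rises appreciably above chance over the
  # tested range, so the threshold is unidentified
  p_top <- A + (B - A) * (1 - exp(-(max(lev) / x0)^m))
  if (x0 > 50 * max(lev) || p_top < A + 0.05 * (B - A))
    stop(degenerate_fit_error(counts,
      "performance indistinguishable from chance across tested levels; no finite threshold"))

  fit <- structure(list(
    coefficients = c(x0 = x0, m = m),
    A = A, B = B,
    p_threshold = p_threshold,
    loglik = -opt$value,
    counts = counts,
    n_trials = sum(n),
    pool_updown = pool_updown,
    call = match.call()
  ), class = "psychfit")
  fit$threshold <- threshold_at(fit, p_threshold)
  fit
}

degenerate_fit_error <- function(counts, msg) {
  structure(class = c("cuepool_degenerate_fit", "error", "condition"),
            list(message = paste0("degenerate fit: ", msg),
                 call = NULL, counts = counts))
}

#' @export
print.psychfit <- function(x, digits = 4, ...) {
  cat("Weibull psychometric fit (maximum likelihood)\n")
  cat(sprintf("  x0 = %.*g, m = %.*g  (A = %g, B = %g fixed)\n",
              digits, x$coefficients[["x0"]], digits, x$coefficients[["m"]],
              x$A, x$B))
  cat(sprintf("  threshold (%.0f%% correct) = %.*g\n",
              100 * x$p_threshold, digits, x$threshold))
  cat(sprintf("  %d trials over %d levels, log-likelihood %.*g\n",
              x$n_trials, nrow(x$counts), digits, x$loglik))
  invisible(x)
}

#' @export
summary.psychfit <- function(object, ...) {
  tab <- object$counts
  tab$fitted <- weibull_p(tab$level, object$coefficients[["x0"]],
                          object$coefficients[["m"]], object$A, object$B)
  structure(list(fit = object, table = tab), class = "summary.psychfit")
}

#' @export
print.summary.psychfit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-level data vs fit:\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) object$coefficients

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n_trials, class = "logLik")
}

#' Predicted proportion correct from a fitted psychometric function
#'
#' @param object a `psychfit` object.
#' @param newdata numeric vector of absolute levels; defaults to the
#'   fitted levels.
#' @param ... unused.
#' @return probabilities at `newdata`.
#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$counts$level else abs(newdata)
  weibull_p(x, object$coefficients[["x0"]], object$coefficients[["m"]],
            object$A, object$B)
}

#' @export
residuals.psychfit <- function(object, ...) {
  object$counts$prop - predict(object)
}

#' Simulate trials from a fitted psychometric function
#'
#' Draws Bernoulli correctness at each requested level from the fitted
#' curve and converts it to signed-level/response records, producing a
#' trial table in the same layout as [simulate_session()].
#'
#' @param object a `psychfit` object.
#' @param nsim number of replicate sessions.
#' @param seed optional integer seed.
#' @param levels signed levels to present (default the fitted absolute
#'   levels, both directions).
#' @param trials_per_level trials per signed level (default 20).
#' @param ... unused.
#' @return a trial data frame, or a list of them when `nsim > 1`.
#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL,
                              levels = NULL, trials_per_level = 20, ...) {
  if (is.null(levels)) levels <- c(-rev(object$counts$level), object$counts$level)
  one <- function() {
    x <- rep(levels, each = trials_per_level)
    p <- predict(object, abs(x))
    ok <- stats::runif(length(x)) < p
    resp <- ifelse(ok, ifelse(x > 0, "up", "down"), ifelse(x > 0, "down", "up"))
    data.frame(level = x, response = resp, correct = ok)
  }
  out <- with_seed(seed, replicate(nsim, one(), simplify = FALSE))
  if (nsim == 1L) out[[1L]] else out
}

#' @export
plot.psychfit <- function(x, xlab = "|control input| (Xc)",
                          ylab = "proportion correct", ...) {
  cf <- x$coefficients
  xs <- seq(0, max(x$counts$level) * 1.2, length.out = 200)
  graphics::plot(xs, weibull_p(xs, cf[["x0"]], cf[["m"]], x$A, x$B),
                 type = "l", ylim = c(x$A - 0.02, 1), xlab = xlab,
                 ylab = ylab, ...)
  graphics::points(x$counts$level, x$counts$prop,
                   cex = 0.5 + sqrt(x$counts$n) / 5, pch = 19)
  graphics::segments(x$threshold, x$A, x$threshold, x$p_threshold, lty = 2)
  graphics::segments(0, x$p_threshold, x$threshold, x$p_threshold, lty = 2)
  invisible(x)
}

# run code with a temporary seed, restoring RNG state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}
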