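#' Weibull psychometric function
#'
#' Probability of a correct response in a forced-choice categorisation task
#' as a function of absolute signal strength, under the Weibull form
#' \deqn{p(x) = A + (B - A)\,\bigl(1 - e^{-(x/x_0)^m}\bigr)}
#' with lower asymptote `A` (chance performance), upper asymptote `B`,
#' scale `x0` and shape (slope) `m`. At `x = x0` the curve passes through
#' `A + (B - A)(1 - 1/e)`, i.e. about 0.816 for the standard 2AFC
#' asymptotes `A = 0.5`, `B = 1`, which is why the 81%-correct point is
#' the conventional threshold criterion.
#'
#' @param x absolute signal level(s), `x >= 0`. Vectorised.
#' @param x0 scale parameter, in the same units as `x`; `x0 > 0`.
#' @param m shape (slope) parameter, dimensionless; `m > 0`.
#' @param A lower asymptote, default 0.5 (chance in 2AFC).
#' @param B upper asymptote, default 1.
#' @return numeric vector of probabilities in `[A, B]`.
#' @seealso [threshold_at()], [fit_psychometric()]
#' @examples
#' weibull_p(0.27, x0 = 0.27, m = 2.5)   # ~0.816 at the scale parameter
#' weibull_p(0, x0 = 0.27, m = 2.5)      # chance floor 0.5
#' @export
weibull_p <- function(x, x0, m, A = 0.5, B = 1.0) {
  check_param(x0, "x0", positive = TRUE)
  check_param(m, "m", positive = TRUE)
  check_param(A, "A"); check_param(B, "B")
  if (A < 0 || A >= B || B > 1)
    stop("asymptotes must satisfy 0 <= A < B <= 1 (got A = ", A,
         ", B = ", B, ")", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and non-negative", call. = FALSE)
  A + (B - A) * (1 - exp(-(x / x0)^m))
}

#' Threshold level at a target probability
#'
#' Inverts the fitted Weibull psychometric function: returns the signal
#' level at which the curve crosses `p_target`. With the default 81%
#' criterion this is the detection/categorisation threshold reported for
#' forced-choice tasks. Closed form:
#' \deqn{x = x_0 \bigl(-\log\tfrac{B - p}{B - A}\bigr)^{1/m}.}
#'
#' @param fit a [`psychfit`][fit_psychometric] object, or any list with
#'   elements `x0`, `m`, `A`, `B`.
#' @param p_target target probability, strictly between `A` and `B`.
#'   Default 0.81.
#' @return the level solving `weibull_p(x) == p_target`.
#' @examples
#' threshold_at(list(x0 = 0.27, m = 2, A = 0.5, B = 1), 0.81)  # ~0.266
#' @export
threshold_at <- function(fit, p_target = 0.81) {
  par <- as_weibull_pars(fit)
  check_param(p_target, "p_target")
  if (p_target <= par$A || p_target >= par$B)
    stop("'p_target' must lie strictly between the asymptotes A = ",
         par$A, " and B = ", par$B, call. = FALSE)
  par$x0 * (-log((par$B - p_target) / (par$B - par$A)))^(1 / par$m)
}

# extract (x0, m, A, B) from a psychfit or a bare list
as_weibull_pars <- function(fit) {
  if (inherits(fit, "psychfit")) {
    cf <- fit$coefficients
    list(x0 = cf[["x0"]], m = cf[["m"]], A = fit$A, B = fit$B)
  } else if (is.list(fit) && all(c("x0", "m") %in% names(fit))) {
    list(x0 = fit$x0, m = fit$m,
         A = if (is.null(fit$A)) 0.5 else fit$A,
         B = if (is.null(fit$B)) 1.0 else fit$B)
  } else {
    stop("'fit' must be a psychfit object or a list with x0, m (and ",
         "optionally A, B)", call. = FALSE)
  }
}

# scalar domain check naming the offending parameter
check_param <- function(value, name, positive = FALSE) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (positive && value <= 0)
    stop("'", name, "' must be positive (got ", value, ")", call. = FALSE)
  invisible(value)
}
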