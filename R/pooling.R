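#' Normalise a bimodal threshold by its unimodal thresholds
#'
#' Re-expresses a bimodal detection threshold in "threshold units": each
#' coordinate is the bimodal threshold divided by one unimodal threshold,
#' so a subject with no bimodal facilitation sits at (1, 1) and stronger
#' facilitation pulls the point towards the origin. All subjects are
#' thereby placed on a common contour for the group pooling fit.
#'
#' @param T_a audio (first-cue) threshold(s), > 0.
#' @param T_m motion (second-cue) threshold(s), > 0.
#' @param T_am bimodal threshold(s), > 0. All three vectorised.
#' @return data frame with columns `u = T_am/T_a`, `v = T_am/T_m`.
#' @examples
#' normalize_thresholds(0.27, 0.21, 0.16)  # ~ (0.593, 0.762)
#' @export
normalize_thresholds <- function(T_a, T_m, T_am) {
  for (nm in c("T_a", "T_m", "T_am")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop("'", nm, "' must be finite and positive", call. = FALSE)
  }
  data.frame(u = T_am / T_a, v = T_am / T_m)
}

#' Predicted combined threshold under Minkowski pooling
#'
#' Given unimodal thresholds `T_i` and pooling exponent `k`, the combined
#' threshold is the unique `T` with \eqn{\sum_i (T/T_i)^k = 1}, i.e.
#' \deqn{T = \Bigl(\sum_i T_i^{-k}\Bigr)^{-1/k}.}
#' `k = 1` is linear (early) summation, `k = 2` optimal reliability-
#' weighted integration, `k ~ 4` probability summation, and `T` tends to
#' `min(T_i)` (no facilitation) as `k` grows.
#'
#' @param unimodal numeric vector of unimodal thresholds, all > 0.
#' @param k pooling exponent, > 0.
#' @return the combined threshold.
#' @examples
#' predict_combined_threshold(c(1, 1), k = 2)        # 1/sqrt(2)
#' predict_combined_threshold(c(0.27, 0.21), k = 2.1) # ~0.168
#' @export
predict_combined_threshold <- function(unimodal, k) {
  if (length(unimodal) == 0L)
    stop("'unimodal' must contain at least one threshold", call. = FALSE)
  if (any(!is.finite(unimodal)) || any(unimodal <= 0))
    stop("'unimodal' thresholds must be finite and positive", call. = FALSE)
  check_param(k, "k", positive = TRUE)
  sum(unimodal^(-k))^(-1 / k)
}

#' Pooling exponent from a single threshold triple
#'
#' Solves \eqn{(T_{am}/T_a)^k + (T_{am}/T_m)^k = 1} for `k`. The left
#' side is strictly decreasing in `k` whenever both ratios are below 1
#' (facilitation), so the root is unique; it is found by bisection
#' (`uniroot`) on `k` in `interval`.
#'
#' @param T_a,T_m,T_am the unimodal and bimodal thresholds (scalars).
#' @param lenient if `TRUE`, a non-facilitating triple
#'   (`T_am >= min(T_a, T_m)`) returns `Inf` (independent channels)
#'   instead of raising an error.
#' @param interval search range for `k`.
#' @return the pooling exponent `k`.
#' @examples
#' k_from_triple(0.27, 0.21, 0.16)     # ~1.81
#' k_from_triple(1, 1, 1 / sqrt(2))    # 2
#' @export
k_from_triple <- function(T_a, T_m, T_am, lenient = FALSE,
                          interval = c(0.1, 64)) {
  check_param(T_a, "T_a", positive = TRUE)
  check_param(T_m, "T_m", positive = TRUE)
  check_param(T_am, "T_am", positive = TRUE)
  u <- T_am / T_a; v <- T_am / T_m
  if (u >= 1 || v >= 1) {
    if (lenient) return(Inf)
    stop("no facilitation: T_am (", T_am, ") is not below min(T_a, T_m) = ",
         min(T_a, T_m), "; k is undefined (independent channels)",
         call. = FALSE)
  }
  f <- function(k) u^k + v^k - 1
  if (f(interval[1]) < 0)
    stop("facilitation too strong: k below search range [",
         interval[1], ", ", interval[2], "]", call. = FALSE)
  if (f(interval[2]) > 0) {
    if (lenient) return(Inf)
    stop("facilitation too weak: k above search range", call. = FALSE)
  }
  stats::uniroot(f, interval, tol = 1e-13)$root
}

#' Classify a pooling exponent into an integration regime
#'
#' Nearest of the canonical regimes: `k = 1` linear summation, `k = 2`
#' optimal (reliability-weighted) integration, `k = 4` probability
#' summation; `k > 8` (including `Inf`) is reported as independent
#' channels.
#'
#' @param k pooling exponent.
#' @return one of `"linear"`, `"optimal"`, `"probability_summation"`,
#'   `"independence"`.
#' @export
classify_regime <- function(k) {
  anchors <- c(linear = 1, optimal = 2, probability_summation = 4)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
    stop("'k' must be a single positive number", call. = FALSE)
  if (k > 8) return("independence")
  names(anchors)[which.min(abs(anchors - k))]
}

#' Fit the group Minkowski pooling exponent
#'
#' Fits a single pooling exponent `k` to a group of normalised bimodal
#' thresholds by least squares on the radial Minkowski residual: `k`
#' minimises \eqn{\sum_j \bigl((u_j^k + v_j^k)^{1/k} - 1\bigr)^2}, i.e.
#' the distance of each subject's point from the unit pooling contour.
#' This objective is symmetric in the two cues and, for a single subject,
#' its minimiser is the exact root found by [k_from_triple()].
#'
#' @param points a data frame with normalised columns `u`, `v` (from
#'   [normalize_thresholds()]), or with raw threshold columns `T_a`,
#'   `T_m`, `T_am` (normalised internally). An optional `subject_id`
#'   column labels residuals.
#' @param strict if `TRUE` (default), any subject with `u >= 1` and
#'   `v >= 1` (no facilitation at all) raises an error naming the
#'   offending subjects; if `FALSE` such points are retained and pull
#'   the fit towards independence.
#' @param interval search range for `k`.
#' @return an object of class `poolingfit`: list with `k`, `regime`,
#'   `residuals` (signed radial residuals), `objective`, `points`.
#' @examples
#' pts <- normalize_thresholds(0.27, 0.21, 0.16)
#' fit_pooling(pts)   # k ~ 1.81, regime "optimal"
#' @export
fit_pooling <- function(points, strict = TRUE, interval = c(0.1, 64)) {
  points <- as.data.frame(points)
  if (all(c("T_a", "T_m", "T_am") %in% names(points))) {
    uv <- normalize_thresholds(points$T_a, points$T_m, points$T_am)
    points <- cbind(points[setdiff(names(points), c("u", "v"))], uv)
  }
  if (!all(c("u", "v") %in% names(points)))
    stop("'points' needs columns u,v or T_a,T_m,T_am", call. = FALSE)
  if (nrow(points) < 1L) stop("need at least one point", call. = FALSE)
  u <- points$u; v <- points$v
  if (any(!is.finite(u)) || any(!is.finite(v)) || any(u <= 0) || any(v <= 0))
    stop("normalised coordinates must be finite and positive", call. = FALSE)
  bad <- u >= 1 & v >= 1
  if (strict && any(bad)) {
    who <- if (!is.null(points$subject_id)) points$subject_id[bad] else which(bad)
    stop("no facilitation for subject(s): ", paste(who, collapse = ", "),
         " (both normalised thresholds >= 1); rerun with strict = FALSE ",
         "to keep them", call. = FALSE)
  }

  radial <- function(k) (u^k + v^k)^(1 / k)
  if (nrow(points) == 1L && !bad[1L]) {
    # exact root: single subject reduces to k_from_triple
    k <- stats::uniroot(function(k) u^k + v^k - 1, interval, tol = 1e-13)$root
  } else {
    obj <- function(k) sum((radial(k) - 1)^2)
    k <- stats::optimize(obj, interval, tol = 1e-10)$minimum
  }
  res <- radial(k) - 1
  structure(list(
    k = k,
    regime = classify_regime(k),
    residuals = stats::setNames(res, points$subject_id),
    objective = sum(res^2),
    points = points,
    call = match.call()
  ), class = "poolingfit")
}

#' @export
print.poolingfit <- function(x, digits = 4, ...) {
  cat("Quick pooling fit (Minkowski exponent)\n")
  cat(sprintf("  k = %.*g  -> regime: %s\n", digits, x$k, x$regime))
  cat(sprintf("  %d subject point(s), sum of squared radial residuals %.*g\n",
              nrow(x$points), digits, x$objective))
  invisible(x)
}

#' @export
coef.poolingfit <- function(object, ...) c(k = object$k)

#' @export
residuals.poolingfit <- function(object, ...) object$residuals

#' Predict a combined threshold from a pooling fit
#'
#' @param object a `poolingfit`.
#' @param unimodal numeric vector of unimodal thresholds.
#' @param ... unused.
#' @return the combined threshold under the fitted exponent.
#' @export
predict.poolingfit <- function(object, unimodal, ...) {
  predict_combined_threshold(unimodal, object$k)
}

#' @export
summary.poolingfit <- function(object, ...) {
  print(object)
  cat("\nResiduals (radial distance from unit contour):\n")
  print(summary(as.numeric(object$residuals)))
  invisible(object)
}

#' @export
plot.poolingfit <- function(x, xlab = "T_am / T_a (threshold units)",
                            ylab = "T_am / T_m (threshold units)", ...) {
  lim <- c(0, max(1.05, x$points$u, x$points$v))
  graphics::plot(x$points$u, x$points$v, xlim = lim, ylim = lim,
                 xlab = xlab, ylab = ylab, pch = 19, ...)
  # fitted iso-threshold contour u^k + v^k = 1
  cu <- seq(1e-3, 1 - 1e-3, length.out = 200)
  graphics::lines(cu, (1 - cu^x$k)^(1 / x$k), lty = 2)
  graphics::segments(0, 1, 1, 0, lty = 3)  # k = 1 reference line
  invisible(x)
}
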