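#' Median absolute tracking error
#'
#' The tracking performance score: the median over time of the absolute
#' difference between the target and the flown altitude. The median (as
#' opposed to the mean) makes the score robust to brief large excursions.
#'
#' @param target target-height series (ft).
#' @param flown flown-height series (ft), same length and alignment.
#' @return the median absolute error (ft).
#' @examples
#' median_abs_error(c(1, 2, 3), c(1, 2, 3))     # 0
#' median_abs_error(c(0, 0, 0), c(0, 1, 100))   # 1
#' @export
median_abs_error <- function(target, flown) {
  if (length(target) != length(flown))
    stop("'target' and 'flown' must be aligned series of equal length (",
         length(target), " vs ", length(flown), ")", call. = FALSE)
  stats::median(abs(target - flown))
}

# check a complete balanced 2^k design; returns replicate count
check_factorial <- function(runs, response, factors, subject) {
  for (col in c(response, factors, subject))
    if (!col %in% names(runs))
      stop("'runs' is missing column '", col, "'", call. = FALSE)
  for (f in factors)
    if (!all(runs[[f]] %in% c(0, 1, FALSE, TRUE)))
      stop("factor '", f, "' must be two-level coded 0/1", call. = FALSE)
  cells <- expand.grid(lapply(factors, function(.) 0:1))
  names(cells) <- factors
  counts <- tapply(seq_len(nrow(runs)),
                   c(runs[subject], lapply(factors, function(f) runs[[f]])),
                   length)
  counts[is.na(counts)] <- 0L
  if (any(counts == 0L)) {
    miss <- which(counts == 0L, arr.ind = TRUE)
    stop("incomplete design: ", sum(counts == 0L), " empty subject x cell ",
         "combination(s); every subject needs all ",
         2^length(factors), " cells", call. = FALSE)
  }
  if (length(unique(as.vector(counts))) > 1L)
    stop("unbalanced design: unequal replicates per subject x cell",
         call. = FALSE)
  invisible(counts[1L])
}

#' Main effects of a within-subject factorial design
#'
#' For each two-level factor, the mean error at each level averaged over
#' all other cells — first within subject, then across subjects — plus
#' the difference `mean(level 0) - mean(level 1)`, i.e. the error
#' reduction attributable to switching the factor on.
#'
#' @param runs run table: one row per subject x cell with a numeric
#'   response and 0/1 factor columns.
#' @param factors character vector of factor column names (default the
#'   experiment-2 labels `e`, `t`, `m`, `d`).
#' @param response response column name.
#' @param subject subject-id column name.
#' @return data frame with columns `factor`, `mean_level0`,
#'   `mean_level1`, `difference`.
#' @export
main_effects <- function(runs, factors = c("e", "t", "m", "d"),
                         response = "median_abs_error",
                         subject = "subject_id") {
  runs <- as.data.frame(runs)
  check_factorial(runs, response, factors, subject)
  out <- lapply(factors, function(f) {
    m0 <- tapply(runs[[response]][runs[[f]] == 0],
                 runs[[subject]][runs[[f]] == 0], mean)
    m1 <- tapply(runs[[response]][runs[[f]] == 1],
                 runs[[subject]][runs[[f]] == 1], mean)
    data.frame(factor = f, mean_level0 = mean(m0), mean_level1 = mean(m1),
               difference = mean(m0) - mean(m1))
  })
  do.call(rbind, out)
}

#' Repeated-measures ANOVA for two-level within-subject factors
#'
#' Per-factor F test with subjects as a random factor: the response is
#' first averaged to subject x factor-level cell means (over all other
#' cells), then \eqn{F = MS_{factor} / MS_{factor \times subject}} with
#' degrees of freedom (1, n_subjects - 1). For a single factor this is
#' algebraically identical to the squared paired t statistic on the
#' subject-level differences.
#'
#' @inheritParams main_effects
#' @return data frame of class `rm_anova` with columns `factor`, `df1`,
#'   `df2`, `F`, `p`.
#' @export
rm_anova <- function(runs, factors = c("e", "t", "m", "d"),
                     response = "median_abs_error",
                     subject = "subject_id") {
  runs <- as.data.frame(runs)
  check_factorial(runs, response, factors, subject)
  subj <- factor(runs[[subject]])
  S <- nlevels(subj)
  if (S < 2L) stop("need at least 2 subjects", call. = FALSE)
  out <- lapply(factors, function(f) {
    M <- tapply(runs[[response]], list(subj, factor(runs[[f]], c(0, 1))), mean)
    grand <- mean(M)
    ss_f <- S * sum((colMeans(M) - grand)^2)
    inter <- M - outer(rowMeans(M), c(1, 1)) -
      matrix(colMeans(M), S, 2, byrow = TRUE) + grand
    ss_fs <- sum(inter^2)
    Fval <- ss_f / (ss_fs / (S - 1))
    data.frame(factor = f, df1 = 1L, df2 = S - 1L, F = Fval,
               p = stats::pf(Fval, 1, S - 1, lower.tail = FALSE))
  })
  structure(do.call(rbind, out), class = c("rm_anova", "data.frame"))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (subjects as random factor)\n")
  y <- as.data.frame(x)
  y$F <- signif(y$F, 4); y$p <- signif(y$p, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Paired comparison of per-subject scores
#'
#' Paired t test of two matched score vectors (e.g. pre- vs
#' post-training error in matching conditions). Sidedness is always an
#' explicit argument. A degenerate case with all differences exactly
#' zero returns `t = 0`, `p = 1` (by convention); constant nonzero
#' differences return `t = +-Inf` with the correspondingly extreme p.
#'
#' @param a,b numeric vectors of per-subject scores, equal length >= 2.
#' @param alternative `"two.sided"`, `"less"` (`a < b`) or `"greater"`.
#' @return list with `t`, `df`, `p`, `mean_diff`, `alternative`.
#' @examples
#' paired_compare(c(10, 9, 11), c(12, 11, 12))
#' @export
paired_compare <- function(a, b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b))
    stop("'a' and 'b' must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = length(d) - 1L, p = 1,
                  mean_diff = 0, alternative = alternative))
    tv <- sign(mean(d)) * Inf
    p <- switch(alternative,
                two.sided = 0,
                less = if (tv < 0) 0 else 1,
                greater = if (tv > 0) 0 else 1)
    return(list(t = tv, df = length(d) - 1L, p = p,
                mean_diff = mean(d), alternative = alternative))
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate),
       alternative = alternative)
}

#' Learning-curve inclusion filter
#'
#' Fits a least-squares line to the mean tracking error over the
#' training phases and computes the predicted improvement from the first
#' to the last phase. A participant is included in the transfer analysis
#' only if that improvement reaches `min_improvement` (default 0.15 ft),
#' ensuring that only participants who actually learned during training
#' enter the pre/post comparison.
#'
#' @param training_errors numeric vector of per-phase mean errors (ft),
#'   ordered T1..T4 (any length >= 2 accepted).
#' @param min_improvement inclusion threshold (ft).
#' @return list with `included` (logical), `slope` (ft/phase, negative =
#'   improving), `improvement` (ft, predicted first-minus-last).
#' @examples
#' learning_filter(c(0.9, 0.8, 0.7, 0.6))  # improvement 0.3 -> included
#' @export
learning_filter <- function(training_errors, min_improvement = 0.15) {
  if (!is.numeric(training_errors) || any(!is.finite(training_errors)))
    stop("'training_errors' must be finite numbers", call. = FALSE)
  if (length(training_errors) < 2L)
    stop("need at least 2 training phases", call. = FALSE)
  check_param(min_improvement, "min_improvement")
  phase <- seq_along(training_errors)
  fit <- stats::lm(training_errors ~ phase)
  pred <- stats::predict(fit, data.frame(phase = range(phase)))
  improvement <- unname(pred[1] - pred[2])
  list(included = improvement >= min_improvement,
       slope = unname(stats::coef(fit)[2]),
       improvement = improvement)
}
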