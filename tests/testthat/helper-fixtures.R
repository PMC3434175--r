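# shared helpers: build trial tables from per-level counts, and
# deterministic "noiseless" sessions with counts rounded from the curve

trials_from_counts <- function(levels, n, correct) {
  stopifnot(length(levels) == length(n), length(n) == length(correct),
            all(correct <= n))
  do.call(rbind, lapply(seq_along(levels), function(i) {
    data.frame(level = levels[i],
               correct = rep(c(TRUE, FALSE), c(correct[i], n[i] - correct[i])))
  }))
}

noiseless_session <- function(x0, m, levels = seq(0.1, 0.5, 0.1), n = 100) {
  p <- weibull_p(levels, x0, m)
  trials_from_counts(levels, rep(n, length(levels)), round(n * p))
}

# binomial log-likelihood of a psychometric parameter pair on count data
loglik_counts <- function(levels, n, k, x0, m, A = 0.5, B = 1) {
  p <- pmin(pmax(weibull_p(levels, x0, m, A, B), A + 1e-12), B - 1e-12)
  sum(k * log(p) + (n - k) * log1p(-p))
}

# random facilitating threshold triple
random_triple <- function() {
  T_a <- stats::runif(1, 0.1, 1)
  T_m <- stats::runif(1, 0.1, 1)
  k <- stats::runif(1, 0.3, 8)
  T_am <- predict_combined_threshold(c(T_a, T_m), k)
  list(T_a = T_a, T_m = T_m, T_am = T_am, k = k)
}
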