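#' Write a forced-choice trial table
#'
#' Comma-delimited text with a versioned comment line and the mandatory
#' header `subject_id,condition,level,response`.
#'
#' @param trials trial data frame (e.g. from [simulate_session()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- as.data.frame(trials)
  if (is.null(trials$response))
    stop("'trials' must contain a 'response' column", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cuepool trial table v1", con)
  utils::write.table(trials[c("subject_id", "condition", "level", "response")],
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a forced-choice trial table
#'
#' Accepts comma- or tab-delimited text with header
#' `subject_id,condition,level,response` and optional leading `#`
#' comment lines. Rows with response `"none"` (no response, or more than
#' one response, during the trial) are retained but flagged `excluded`;
#' the psychometric fitter discounts them. A derived `correct` column is
#' added (`NA` for excluded rows).
#'
#' @param path input file.
#' @return data frame with columns `subject_id`, `condition`, `level`,
#'   `response`, `correct`, `excluded`.
#' @section Errors:
#' A malformed row (non-numeric, zero or non-finite level; unknown
#' condition or response label) raises an error naming the offending
#' line number.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
  body_idx <- which(!is_comment)
  if (length(body_idx) == 0L) stop("no header found in ", path, call. = FALSE)
  header_line <- lines[body_idx[1]]
  sep <- if (grepl("\t", header_line)) "\t" else ","
  df <- utils::read.table(text = lines[body_idx], header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = c(level = "character"))
  need <- c("subject_id", "condition", "level", "response")
  if (!all(need %in% names(df)))
    stop("invalid header: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  level <- suppressWarnings(as.numeric(df$level))
  line_of <- function(i) body_idx[i + 1L]  # +1 for the header row
  bad <- which(!is.finite(level) | level == 0)
  if (length(bad))
    stop("malformed row at line ", line_of(bad[1]),
         ": level must be a nonzero finite number (got '",
         df$level[bad[1]], "')", call. = FALSE)
  df$level <- level
  bad <- which(!df$condition %in% c("audio", "motion", "both"))
  if (length(bad))
    stop("malformed row at line ", line_of(bad[1]),
         ": unknown condition label '", df$condition[bad[1]], "'",
         call. = FALSE)
  bad <- which(!df$response %in% c("up", "down", "none"))
  if (length(bad))
    stop("malformed row at line ", line_of(bad[1]),
         ": unknown response label '", df$response[bad[1]], "'",
         call. = FALSE)
  df$excluded <- df$response == "none"
  df$correct <- ifelse(df$excluded, NA,
                       (df$response == "up") == (df$level > 0))
  df
}

#' Write / read a threshold-triple table
#'
#' Comma-delimited with header `subject_id,T_a,T_m,T_am`.
#'
#' @param thresholds data frame with those columns.
#' @param path file path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_thresholds <- function(thresholds, path) {
  need <- c("subject_id", "T_a", "T_m", "T_am")
  if (!all(need %in% names(thresholds)))
    stop("'thresholds' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cuepool threshold table v1", con)
  utils::write.table(thresholds[need], con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "T_a", "T_m", "T_am")
  if (!all(need %in% names(df)))
    stop("invalid header: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  for (col in c("T_a", "T_m", "T_am"))
    if (any(!is.finite(df[[col]]) | df[[col]] <= 0))
      stop("thresholds must be finite and positive (column ", col, ")",
           call. = FALSE)
  df
}

#' Serialise a fit as a flat key = value text record
#'
#' @param fit a `psychfit` or `poolingfit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  kv <- if (inherits(fit, "psychfit")) {
    c(type = "psychfit", x0 = fit$coefficients[["x0"]],
      m = fit$coefficients[["m"]], A = fit$A, B = fit$B,
      threshold = fit$threshold, p_threshold = fit$p_threshold,
      loglik = fit$loglik, n_trials = fit$n_trials)
  } else if (inherits(fit, "poolingfit")) {
    c(type = "poolingfit", k = fit$k, regime = fit$regime,
      objective = fit$objective, n_points = nrow(fit$points))
  } else stop("'fit' must be a psychfit or poolingfit", call. = FALSE)
  writeLines(paste(names(kv), unname(kv), sep = " = "), path)
  invisible(path)
}

#' Default configuration for the detection-experiment replica
#'
#' Collects the study constants into one editable list: the ten signed
#' levels `+-0.1..0.5`, the 81% threshold criterion, ten subjects, and an
#' observer whose default noise puts the unimodal thresholds near the
#' reported 0.27 / 0.21 magnitudes.
#'
#' @param seed master seed.
#' @param n_subjects cohort size.
#' @param observer_kind observer mechanism (see [observer_spec()]).
#' @param sigma_a,sigma_m,m_channel observer parameters.
#' @param heterogeneity between-subject log-normal spread of the sigmas.
#' @param trials_per_level trials per signed level and condition.
#' @param levels signed level set.
#' @param p_threshold threshold criterion.
#' @return a named list of class `exp1_config`.
#' @export
exp1_config <- function(seed = 1, n_subjects = 10,
                        observer_kind = "optimal_gaussian",
                        sigma_a = 0.27 / stats::qnorm(0.81),
                        sigma_m = 0.21 / stats::qnorm(0.81),
                        m_channel = 4, heterogeneity = 0.15,
                        trials_per_level = 500,
                        levels = c(-(5:1), 1:5) / 10,
                        p_threshold = 0.81) {
  structure(list(seed = seed, n_subjects = n_subjects,
                 observer_kind = observer_kind, sigma_a = sigma_a,
                 sigma_m = sigma_m, m_channel = m_channel,
                 heterogeneity = heterogeneity,
                 trials_per_level = trials_per_level, levels = levels,
                 p_threshold = p_threshold), class = "exp1_config")
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys override the [exp1_config()] defaults. Unknown
#' keys are rejected (a typo should fail loudly, not fall back to a
#' default silently).
#'
#' @param path YAML file.
#' @return an `exp1_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- exp1_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(raw)] <- raw
  defaults
}

#' Run the detection-experiment analysis chain end to end
#'
#' Simulates a cohort of observers, runs each through the forced-choice
#' session, fits a Weibull psychometric function per subject and cue
#' condition, extracts the 81% thresholds, normalises the bimodal
#' thresholds into threshold units, and fits the group Minkowski pooling
#' exponent. Fully deterministic given the master seed.
#'
#' @param config an [exp1_config()] (or the list from [read_config()]).
#' @return an object of class `exp1_replica`: list with `config`,
#'   `thresholds` (per-subject triples), `pooling` (a
#'   [`poolingfit`][fit_pooling]), `k`, `regime`.
#' @examples
#' \donttest{
#' rep <- run_experiment1_replica(exp1_config(n_subjects = 4,
#'                                            trials_per_level = 100))
#' rep$k  # ~2 for the optimal-gaussian observer
#' }
#' @export
run_experiment1_replica <- function(config = exp1_config()) {
  stopifnot(is.list(config))
  if (config$trials_per_level < 1)
    stop("insufficient data: trials_per_level must be >= 1 (psychometric ",
         "stage needs trials at 2+ levels)", call. = FALSE)
  base <- observer_spec(config$observer_kind, sigma_a = config$sigma_a,
                        sigma_m = config$sigma_m,
                        m_channel = config$m_channel)
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max / 2, config$n_subjects + 1))
  cohort <- make_cohort(config$n_subjects, base, config$heterogeneity,
                        seed = seeds[1])
  design <- session_design(levels = config$levels,
                           trials_per_level = config$trials_per_level)
  triples <- lapply(seq_along(cohort), function(i) {
    tryCatch(
      observer_threshold_triple(cohort[[i]], design, seed = seeds[i + 1]),
      error = function(e) stop("psychometric stage failed for subject ",
                               cohort[[i]]$subject_id, ": ",
                               conditionMessage(e), call. = FALSE))
  })
  thresholds <- do.call(rbind, triples)
  pooling <- tryCatch(fit_pooling(thresholds, strict = FALSE),
                      error = function(e) stop("pooling stage failed: ",
                                               conditionMessage(e),
                                               call. = FALSE))
  structure(list(config = config, cohort = cohort, thresholds = thresholds,
                 pooling = pooling, k = pooling$k,
                 regime = pooling$regime), class = "exp1_replica")
}

#' @export
print.exp1_replica <- function(x, ...) {
  cat("Detection-experiment replica\n")
  cat(sprintf("  %d x %s observers, %d trials/level\n",
              x$config$n_subjects, x$config$observer_kind,
              x$config$trials_per_level))
  cat(sprintf("  mean thresholds: T_a = %.3f, T_m = %.3f, T_am = %.3f\n",
              mean(x$thresholds$T_a), mean(x$thresholds$T_m),
              mean(x$thresholds$T_am)))
  cat(sprintf("  pooling exponent k = %.3f -> %s\n", x$k, x$regime))
  invisible(x)
}

#' Write the canonical fixture bundle
#'
#' Emits small, byte-stable (given `seed`) text datasets used by the
#' test suite and examples: one forced-choice session per observer kind,
#' a threshold table whose first row is a synthetic triple constructed
#' at the reported representative magnitudes (T_a = 0.27, T_m = 0.21,
#' T_am = 0.16), a short target path, and a small factorial tracking
#' cohort.
#'
#' @param outdir writable directory (created if missing).
#' @param seed integer seed.
#' @return named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(outdir, seed = 1) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c()
  kinds <- c("optimal_gaussian", "linear_late_noise", "probability_summation")
  design <- session_design(trials_per_level = 20)
  for (i in seq_along(kinds)) {
    obs <- observer_spec(kinds[i], subject_id = paste0("S", i))
    tr <- simulate_session(obs, design, seed = seed + i)
    f <- file.path(outdir, paste0("trials_", kinds[i], ".csv"))
    write_trials(tr, f)
    paths[paste0("trials_", kinds[i])] <- f
  }
  th <- data.frame(subject_id = c("S4_synthetic", "S5_synthetic"),
                   T_a = c(0.27, 0.30), T_m = c(0.21, 0.24),
                   T_am = c(0.16, 0.19))
  f <- file.path(outdir, "thresholds_synthetic.csv")
  write_thresholds(th, f)
  paths["thresholds"] <- f

  path_df <- target_path(duration = 30, dt = 0.1, seed = seed)
  f <- file.path(outdir, "target_path.csv")
  utils::write.csv(path_df, f, row.names = FALSE)
  paths["target_path"] <- f

  runs <- simulate_factorial_runs(n_subjects = 2, duration = 10, dt = 0.05,
                                  seed = seed)
  f <- file.path(outdir, "tracking_runs.csv")
  utils::write.csv(runs, f, row.names = FALSE)
  paths["tracking_runs"] <- f
  invisible(paths)
}
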