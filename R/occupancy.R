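# Daily time spent at home: the same cluster-then-pattern machinery applied
# to 48-slot daily vectors. "Time at home" is sensor-observed active time:
# 30 minutes per binarized-active slot of the cluster pattern, so sleep
# hours (sensor-inactive) are not counted.

#' Time at home of one daily cluster pattern
#'
#' @param pattern binary vector of length 48 (or a `cluster_pattern`).
#' @return minutes at home in \[0, 1440\]: 30 x (number of active slots).
#' @export
time_at_home <- function(pattern) {
  if (inherits(pattern, "cluster_pattern")) pattern <- pattern$slots
  if (length(pattern) != 48L) stop("daily pattern must have 48 slots", call. = FALSE)
  if (!all(pattern %in% c(0L, 1L))) stop("pattern must be binary", call. = FALSE)
  30 * sum(pattern)
}

#' Cluster-weighted household time at home
#'
#' @param patterns list of `cluster_pattern` objects (48 slots each), or a
#'   numeric vector of per-cluster minutes when `weights` is given.
#' @param weights optional cluster weights (renormalized internally).
#' @return weighted minutes-at-home per day.
#' @export
weighted_home_time <- function(patterns, weights = NULL) {
  if (is.numeric(patterns)) {
    values <- patterns
    if (is.null(weights)) stop("weights required with numeric input", call. = FALSE)
  } else {
    patterns <- Filter(Negate(is.null), patterns)
    if (length(patterns) == 0L) stop("no patterns supplied", call. = FALSE)
    values <- vapply(patterns, time_at_home, numeric(1))
    if (is.null(weights))
      weights <- vapply(patterns, `[[`, numeric(1), "weight")
  }
  weights <- weights / sum(weights)
  sum(weights * values)
}

#' One-call household time at home from daily vectors
#'
#' Fits the daily-vector mixture and returns the cluster-weighted minutes
#' spent at home per day.
#'
#' @inheritParams fit_daily_clusters
#' @return numeric minutes with attributes `k` and `n_days`, or an
#'   exclusion sentinel.
#' @export
household_home_time <- function(x, k_max = 6L, seed = 1L, min_records = 10L) {
  X <- if (inherits(x, "daily_activity")) x$slots else as.matrix(x)
  model <- fit_daily_clusters(X, k_max = k_max, seed = seed,
                              min_records = min_records)
  if (is_excluded(model)) return(model)
  value <- weighted_home_time(cluster_patterns(model, X))
  attr(value, "k") <- model$k
  attr(value, "n_days") <- model$n
  value
}
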