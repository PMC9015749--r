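# Sleep indicator extraction: cluster patterns -> longest inactive run ->
# cluster-weighted household indicators.
#
# Indicator axis: minutes on the 20:00-anchored sleep-cycle axis, where 0 is
# 20:00 of day 0 and 960 is 12:00 of day 1. Use axis_to_midnight() /
# format_hhmm() for clock display.

#' Extract the activation pattern of one cluster
#'
#' The pattern marks a slot active when the mean activation of the member
#' records exceeds 0.5 (strictly: a mean of exactly 0.5 is inactive). The
#' cluster weight is the fraction of all records in the stratum assigned to
#' this cluster.
#'
#' @param member_records binary matrix of the records assigned to one
#'   cluster (rows = records, 32 or 48 columns).
#' @param n_total total records in the household-stratum (for the weight);
#'   defaults to `nrow(member_records)`.
#' @return list of class `cluster_pattern` with `slots` (0/1 integer
#'   vector), `weight` and `n_members`.
#' @export
extract_pattern <- function(member_records, n_total = nrow(member_records)) {
  member_records <- as.matrix(member_records)
  if (nrow(member_records) < 1L) stop("empty cluster", call. = FALSE)
  structure(list(slots = as.integer(colMeans(member_records) > 0.5),
                 weight = nrow(member_records) / n_total,
                 n_members = nrow(member_records)),
            class = "cluster_pattern")
}

# All patterns of a fitted mixture, in component order.
cluster_patterns <- function(model, X) {
  lapply(seq_len(model$k), function(j) {
    members <- X[model$assign == j, , drop = FALSE]
    if (nrow(members) == 0L) return(NULL)
    extract_pattern(members, n_total = nrow(X))
  })
}

#' Locate the sleep interval in a 32-slot cycle pattern
#'
#' Scans the maximal runs of consecutive inactive slots that are terminated
#' by at least one active slot and selects the longest (earliest start on
#' ties). The run's first slot gives the sleep time, the first active slot
#' after it the wake-up time, and the run length the sleep duration -- all
#' in minutes on the 20:00-anchored axis (0 = 20:00, 960 = 12:00 next day).
#' A run may begin at slot 0 (sleep time 20:00, the earliest allowed). A
#' pattern that is all active, all inactive, or whose only inactive runs
#' reach slot 31 without a subsequent activation (household likely away)
#' yields no sleep interval: an exclusion sentinel (reason
#' `"no_sleep_interval"`) is returned.
#'
#' @param pattern binary vector of length 32 (or a `cluster_pattern`).
#' @return list of class `sleep_indicators` with `sleep_time`, `wake_time`,
#'   `duration` (minutes, multiples of 30), or an exclusion sentinel.
#' @export
detect_sleep_interval <- function(pattern) {
  if (inherits(pattern, "cluster_pattern")) pattern <- pattern$slots
  if (length(pattern) != 32L) stop("sleep-cycle pattern must have 32 slots", call. = FALSE)
  if (!all(pattern %in% c(0L, 1L))) stop("pattern must be binary", call. = FALSE)
  r <- rle(as.integer(pattern))
  nrun <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values == 0L & seq_len(nrun) < nrun)  # next run is active
  if (length(cand) == 0L) return(excluded("no_sleep_interval"))
  best <- cand[which.max(r$lengths[cand])]  # earliest on ties
  structure(list(sleep_time = 30 * (starts[best] - 1L),
                 wake_time = 30 * ends[best],
                 duration = 30 * r$lengths[best]),
            class = "sleep_indicators")
}

#' @export
print.sleep_indicators <- function(x, ...) {
  cat(sprintf("<sleep_indicators> sleep %s, wake %s, duration %.0f min\n",
              format_hhmm(axis_to_midnight(x$sleep_time)),
              format_hhmm(axis_to_midnight(x$wake_time)), x$duration))
  invisible(x)
}

#' Cluster-weighted household sleep indicators
#'
#' Combines the sleep indicators of each cluster pattern into one household
#' value per indicator, weighting by the fraction of records assigned to
#' the cluster. Patterns without a detectable sleep interval are dropped
#' and the remaining weights renormalized; if no valid pattern remains the
#' household is excluded from the stratum.
#'
#' @param patterns list of `cluster_pattern` objects (each with 32 slots).
#' @return `sleep_indicators` (weighted; values need not be multiples of
#'   30) with attribute `n_valid`, or an exclusion sentinel (reason
#'   `"no_valid_pattern"`).
#' @export
weighted_indicators <- function(patterns) {
  patterns <- Filter(Negate(is.null), patterns)
  if (length(patterns) == 0L) stop("no patterns supplied", call. = FALSE)
  ind <- lapply(patterns, detect_sleep_interval)
  keep <- !vapply(ind, is_excluded, logical(1))
  if (!any(keep)) return(excluded("no_valid_pattern"))
  w <- vapply(patterns[keep], `[[`, numeric(1), "weight")
  w <- w / sum(w)
  agg <- function(field) sum(w * vapply(ind[keep], `[[`, numeric(1), field))
  structure(list(sleep_time = agg("sleep_time"),
                 wake_time = agg("wake_time"),
                 duration = agg("duration")),
            class = "sleep_indicators", n_valid = sum(keep))
}

#' One-call household sleep indicators from cycles
#'
#' Convenience wrapper: fit the cycle mixture, extract per-cluster patterns
#' and return the weighted household indicators.
#'
#' @inheritParams fit_cycle_clusters
#' @return `sleep_indicators` with attributes `k` and `n_cycles`, or an
#'   exclusion sentinel.
#' @export
household_sleep_indicators <- function(x, k_max = 6L, seed = 1L,
                                       min_records = 10L) {
  X <- if (inherits(x, "sleep_cycles")) x$cycles else as.matrix(x)
  model <- fit_cycle_clusters(X, k_max = k_max, seed = seed,
                              min_records = min_records)
  if (is_excluded(model)) return(model)
  out <- weighted_indicators(cluster_patterns(model, X))
  if (is_excluded(out)) return(out)
  attr(out, "k") <- model$k
  attr(out, "n_cycles") <- model$n
  out
}
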