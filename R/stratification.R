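# Calendar stratification: seasons, weekdays and their cross, plus the
# day-attribution convention for cycle-based indicators.

#' Assign calendar dates to seasons
#'
#' Season windows (inclusive): winter Jan 1 - Mar 21, spring Mar 22 -
#' Jun 21, summer Jun 22 - Sep 21, fall Sep 22 - Dec 21. Dec 22-31 falls
#' outside every window and maps to `NA` (those dates are dropped from
#' season-based strata); Feb 29 is winter.
#'
#' @param dates `Date` vector.
#' @return factor with levels winter/spring/summer/fall (`NA` for
#'   Dec 22-31).
#' @export
assign_season <- function(dates) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  m <- lt$mon + 1L
  d <- lt$mday
  out <- rep(NA_character_, length(dates))
  out[m %in% c(1L, 2L) | (m == 3L & d <= 21L)] <- "winter"
  out[(m == 3L & d >= 22L) | m %in% c(4L, 5L) | (m == 6L & d <= 21L)] <- "spring"
  out[(m == 6L & d >= 22L) | m %in% c(7L, 8L) | (m == 9L & d <= 21L)] <- "summer"
  out[(m == 9L & d >= 22L) | m %in% c(10L, 11L) | (m == 12L & d <= 21L)] <- "fall"
  factor(out, levels = season_levels)
}

#' Weekday labels of dates
#'
#' @param dates `Date` vector.
#' @return factor with levels Mon..Sun (ISO weekday order).
#' @export
weekday_of <- function(dates) {
  factor(weekday_levels[iso_wday(as.Date(dates))], levels = weekday_levels)
}

#' Attribution date of a cycle-based indicator
#'
#' A sleep cycle spans two calendar days: sleep time and sleep duration
#' belong to the evening (day 0, the cycle date) while the wake-up time
#' belongs to the following morning (day 1). Time at home uses the daily
#' vector's own date and is unaffected.
#'
#' @param cycle_date `Date` of day 0.
#' @param indicator one of `"sleep_time"`, `"duration"`, `"wake_time"`.
#' @return `Date` vector used for stratification.
#' @export
attribute_cycle <- function(cycle_date, indicator) {
  indicator <- match.arg(indicator, c("sleep_time", "duration", "wake_time"))
  cycle_date <- as.Date(cycle_date)
  if (indicator == "wake_time") cycle_date + 1L else cycle_date
}

#' Stratum labels for dates under a scheme
#'
#' Schemes: `"all"` (single stratum), `"weekday"` (Mon..Sun),
#' `"season"` (four seasons; Dec 22-31 -> `NA`) and `"season_weekday"`
#' (the 28 season x weekday cells, labelled `"winter:Mon"` etc.).
#'
#' @param dates `Date` vector.
#' @param scheme stratification scheme.
#' @return factor of stratum labels; `NA` marks dates outside every stratum
#'   (dropped by [partition_dates()]).
#' @export
stratum_of <- function(dates, scheme = c("all", "weekday", "season", "season_weekday")) {
  scheme <- match.arg(scheme)
  dates <- as.Date(dates)
  switch(scheme,
    all = factor(rep("all", length(dates)), levels = "all"),
    weekday = factor(weekday_levels[iso_wday(dates)], levels = weekday_levels),
    season = assign_season(dates),
    season_weekday = {
      s <- assign_season(dates)
      w <- weekday_levels[iso_wday(dates)]
      lv <- as.vector(t(outer(season_levels, weekday_levels, paste, sep = ":")))
      factor(ifelse(is.na(s), NA, paste(as.character(s), w, sep = ":")),
             levels = lv)
    })
}

#' Partition dated records into strata
#'
#' @param dates `Date` vector, one per record.
#' @inheritParams stratum_of
#' @return named list mapping each non-empty stratum label to the integer
#'   indices of its records; records with `NA` strata (Dec 22-31 under
#'   season schemes) appear in none.
#' @export
partition_dates <- function(dates, scheme = "weekday") {
  f <- stratum_of(dates, scheme)
  idx <- split(seq_along(dates), f, drop = FALSE)
  idx[vapply(idx, length, integer(1)) > 0L]
}

# Split a season_weekday label back into its two factors.
split_season_weekday <- function(labels) {
  parts <- strsplit(as.character(labels), ":", fixed = TRUE)
  data.table::data.table(
    season = factor(vapply(parts, `[`, character(1), 1L), levels = season_levels),
    weekday = factor(vapply(parts, `[`, character(1), 2L), levels = weekday_levels))
}
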