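# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic child seed; stays inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 1e6) * 2017 + 104729 * (as.numeric(index) %% 1e4)) %% 2147483647L
}

# ISO weekday: 1 = Monday ... 7 = Sunday. 1970-01-01 was a Thursday (4).
iso_wday <- function(dates) {
  ((as.integer(as.Date(dates)) + 3L) %% 7L) + 1L
}

weekday_levels <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
season_levels  <- c("winter", "spring", "summer", "fall")

#' Format minutes-after-midnight as hh:mm
#'
#' Values of 1440 or more wrap past midnight (e.g. 1360 -> "22:40",
#' 1500 -> "01:00").
#'
#' @param minutes numeric vector of minutes after midnight.
#' @return character vector in `"%H:%M"` form.
#' @export
format_hhmm <- function(minutes) {
  m <- round(minutes) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

#' Convert between midnight- and 20:00-anchored minute axes
#'
#' Sleep-cycle indicators live on an axis where 0 = 20:00 of day 0 and
#' 960 = 12:00 of day 1. `axis_to_midnight()` maps back to conventional
#' minutes after midnight (values < 240 on the axis fall before midnight and
#' map into \[1200, 1440); values >= 240 map to the next morning's clock).
#'
#' @param minutes_after_midnight clock minutes; values in \[1200, 1440) are
#'   evening, \[0, 720) morning.
#' @param axis_minutes minutes on the 20:00-anchored axis, in \[0, 960\].
#' @return numeric vector on the other axis.
#' @export
midnight_to_axis <- function(minutes_after_midnight) {
  m <- minutes_after_midnight %% 1440
  ifelse(m >= 1200, m - 1200, m + 240)
}

#' @rdname midnight_to_axis
#' @export
axis_to_midnight <- function(axis_minutes) {
  ifelse(axis_minutes < 240, axis_minutes + 1200, axis_minutes - 240)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sentinel for "household excluded from this stratum" outcomes: signaled,
# not raised, so the pipeline can log the reason and move on.
excluded <- function(reason) {
  structure(list(reason = reason), class = "stratum_excluded")
}

#' Test for a stratum-exclusion sentinel
#'
#' Cluster fits and indicator extractors return an exclusion sentinel (with
#' an attached `$reason`) instead of raising when a household cannot
#' contribute to a stratum (too few records, no valid sleep pattern).
#'
#' @param x any object.
#' @return `TRUE` for exclusion sentinels.
#' @export
is_excluded <- function(x) inherits(x, "stratum_excluded")

exclusion_reason <- function(x) if (is_excluded(x)) x$reason else NA_character_

stop_config <- function(field, msg) {
  stop(sprintf("invalid household configuration: field '%s' %s", field, msg),
       call. = FALSE)
}
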