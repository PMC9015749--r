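# Preprocessing: 5-minute streams -> binarized 30-minute daily activity
# vectors -> 32-slot sleep cycles, plus the cohort eligibility filter.

# Integer clock helpers on naive-UTC POSIXct timestamps.
ts_seconds <- function(ts) as.numeric(ts)
ts_check_grid <- function(ts) {
  s <- ts_seconds(ts)
  if (any(s %% 300 != 0))
    stop("off-grid timestamp: readings must lie on the 5-minute grid (:00/:05/...)",
         call. = FALSE)
  invisible(TRUE)
}
ts_date <- function(ts) as.Date(floor(ts_seconds(ts) / 86400), origin = "1970-01-01")
ts_slot <- function(ts) as.integer(((ts_seconds(ts) %/% 60) %% 1440) %/% 30)

#' Aggregate one household-day of readings into 48 slot scores
#'
#' Each (sensor, 5-minute interval) activation contributes 1 to the score of
#' the 30-minute slot containing it: one sensor active for four consecutive
#' 5-minute intervals scores 4, as do four sensors each active once.
#' Slots are half-open `[00:00 + 30i, 00:00 + 30(i+1))` in local clock time.
#' Missing readings score 0.
#'
#' @param readings `data.table`/data.frame with columns `household_id`,
#'   `timestamp` (POSIXct on the 5-minute grid), `sensor_id`, `motion`; all
#'   rows must share one household and one calendar date.
#' @return integer vector of length 48 (slot scores).
#' @export
aggregate_to_slots <- function(readings) {
  readings <- data.table::as.data.table(readings)
  if (nrow(readings) == 0L) return(integer(48))
  ts_check_grid(readings$timestamp)
  if (length(unique(readings$household_id)) != 1L)
    stop("aggregate_to_slots expects a single household", call. = FALSE)
  d <- ts_date(readings$timestamp)
  if (length(unique(d)) != 1L)
    stop("aggregate_to_slots expects a single calendar date", call. = FALSE)
  if (anyDuplicated(readings, by = c("household_id", "timestamp", "sensor_id")))
    stop("duplicate (household, timestamp, sensor) readings", call. = FALSE)
  slot <- ts_slot(readings$timestamp)
  as.integer(tabulate(slot[readings$motion == 1L] + 1L, nbins = 48L))
}

#' Binarize slot scores at an activation threshold
#'
#' A slot is active when its score reaches the threshold (default 4);
#' lower-scoring slots are treated as noise.
#'
#' @param slot_scores non-negative integer scores (length 48 in pipeline
#'   use, any length accepted).
#' @param threshold activation threshold (score >= threshold is active).
#' @return integer 0/1 vector of the same length.
#' @export
binarize <- function(slot_scores, threshold = 4L) {
  if (any(slot_scores < 0)) stop("negative slot score", call. = FALSE)
  as.integer(slot_scores >= threshold)
}

#' Cohort eligibility filter
#'
#' A household enters the analysis when it has at least `min_days` days of
#' data, at least `min_sensors` motion sensors and at most `max_occupants`
#' residents.
#'
#' @param days_available,n_sensors,n_occupants household metadata
#'   (vectorized).
#' @param min_days,min_sensors,max_occupants thresholds; defaults 300 days,
#'   6 sensors, 4 residents.
#' @return logical vector.
#' @export
check_eligibility <- function(days_available, n_sensors, n_occupants,
                              min_days = 300L, min_sensors = 6L,
                              max_occupants = 4L) {
  if (any(days_available < 0) || any(n_sensors < 0) || any(n_occupants < 0))
    stop("household metadata counts must be non-negative", call. = FALSE)
  days_available >= min_days & n_sensors >= min_sensors & n_occupants <= max_occupants
}

#' Build binarized daily activity vectors for a whole stream
#'
#' Bulk form of [aggregate_to_slots()] + [binarize()]: returns one 48-slot
#' record per household-day present in the stream. Days with no readings at
#' all are treated as missing (device offline), not as inactive days;
#' partially reporting days are kept with absent readings scoring 0.
#'
#' @param readings readings table (see [read_sensor_csv()]); may span
#'   several households.
#' @param threshold activation threshold passed to [binarize()].
#' @return object of class `daily_activity`: list with `index` (a
#'   `data.table` of `household_id`, `date`), `scores` (integer matrix
#'   n x 48) and `slots` (binary matrix n x 48).
#' @export
build_daily_vectors <- function(readings, threshold = 4L) {
  readings <- data.table::as.data.table(readings)
  if (nrow(readings) == 0L) stop("empty readings", call. = FALSE)
  ts_check_grid(readings$timestamp)
  if (anyDuplicated(readings, by = c("household_id", "timestamp", "sensor_id")))
    stop("duplicate (household, timestamp, sensor) readings", call. = FALSE)
  work <- data.table::data.table(
    household_id = readings$household_id,
    date = ts_date(readings$timestamp),
    slot = ts_slot(readings$timestamp),
    motion = readings$motion)
  index <- unique(work[, .(household_id, date)])
  data.table::setkey(index, household_id, date)
  index[, row := .I]
  agg <- work[motion == 1L, .N, by = .(household_id, date, slot)]
  scores <- matrix(0L, nrow = nrow(index), ncol = 48L)
  if (nrow(agg)) {
    r <- index[agg, row, on = c("household_id", "date")]
    scores[cbind(r, agg$slot + 1L)] <- agg$N
  }
  slots <- matrix(as.integer(scores >= threshold), nrow = nrow(index))
  structure(list(index = index[, .(household_id, date)],
                 scores = scores, slots = slots, threshold = threshold),
            class = "daily_activity")
}

#' @export
print.daily_activity <- function(x, ...) {
  cat(sprintf("<daily_activity> %d household-days, %d households, threshold %d\n",
              nrow(x$index), length(unique(x$index$household_id)), x$threshold))
  invisible(x)
}

#' Splice daily vectors into 32-slot sleep cycles
#'
#' For every pair of calendar-consecutive days of a household, the sleep
#' cycle concatenates the evening of day 0 (slots 40-47, 20:00-24:00) with
#' the morning of day 1 (slots 0-23, 00:00-12:00); the noon-20:00 window is
#' disregarded. Gaps in the date sequence produce no cycle and are counted
#' in the `n_gaps` attribute.
#'
#' @param daily a `daily_activity` object.
#' @return object of class `sleep_cycles`: list with `index`
#'   (`household_id`, `cycle_date` = date of day 0) and `cycles` (binary
#'   matrix n x 32).
#' @export
build_sleep_cycles <- function(daily) {
  stopifnot(inherits(daily, "daily_activity"))
  idx <- data.table::copy(daily$index)[, row := .I]
  data.table::setorder(idx, household_id, date)
  same_house <- idx$household_id[-nrow(idx)] == idx$household_id[-1L]
  consecutive <- diff(as.integer(idx$date)) == 1L
  first <- which(c(same_house & consecutive, FALSE))
  n_gaps <- sum(c(same_house & !consecutive, FALSE))
  if (length(first) == 0L) {
    cycles <- matrix(integer(0), ncol = 32L)
    index <- data.table::data.table(household_id = character(0),
                                    cycle_date = as.Date(character(0)))
  } else {
    r0 <- idx$row[first]
    r1 <- idx$row[first + 1L]
    cycles <- cbind(daily$slots[r0, 41:48, drop = FALSE],
                    daily$slots[r1, 1:24, drop = FALSE])
    index <- data.table::data.table(household_id = idx$household_id[first],
                                    cycle_date = idx$date[first])
  }
  structure(list(index = index, cycles = cycles, n_gaps = n_gaps),
            class = "sleep_cycles")
}

#' @export
print.sleep_cycles <- function(x, ...) {
  cat(sprintf("<sleep_cycles> %d cycles, %d households (%d date gaps skipped)\n",
              nrow(x$index), length(unique(x$index$household_id)), x$n_gaps))
  invisible(x)
}

#' Write daily-vector and cycle CSVs
#'
#' Daily vectors are written as `household_id,date,s00..s47`; cycles as
#' `household_id,cycle_date,c00..c31` (binary cells).
#'
#' @param x a `daily_activity` or `sleep_cycles` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(x, path) {
  stopifnot(inherits(x, "daily_activity"))
  m <- data.table::as.data.table(x$slots)
  data.table::setnames(m, sprintf("s%02d", 0:47))
  data.table::fwrite(cbind(x$index, m), path)
  invisible(path)
}

#' @rdname write_daily_csv
#' @export
write_cycle_csv <- function(x, path) {
  stopifnot(inherits(x, "sleep_cycles"))
  m <- data.table::as.data.table(x$cycles)
  data.table::setnames(m, sprintf("c%02d", 0:31))
  data.table::fwrite(cbind(x$index, m), path)
  invisible(path)
}
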