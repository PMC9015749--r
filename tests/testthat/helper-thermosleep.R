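# Shared fixtures: everything is generated in code at test time.

# Readings table from (sensor, clock-minute) activation pairs on one date;
# inactive grid points are omitted unless fill_grid = TRUE.
make_readings <- function(date = as.Date("2021-03-01"), active = list(),
                          sensors = c("S01"), fill_grid = FALSE,
                          household_id = "HH001") {
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  rows <- list()
  if (fill_grid) {
    grid <- expand.grid(minute = seq(0, 1435, by = 5), sensor_id = sensors,
                        stringsAsFactors = FALSE)
    rows[[1]] <- data.table::data.table(
      household_id = household_id, timestamp = t0 + grid$minute * 60,
      sensor_id = grid$sensor_id, motion = 0L)
  }
  for (a in active) {
    rows[[length(rows) + 1]] <- data.table::data.table(
      household_id = household_id, timestamp = t0 + a$minutes * 60,
      sensor_id = a$sensor, motion = 1L)
  }
  out <- data.table::rbindlist(rows)
  if (fill_grid) {
    # activations override the zero grid
    out <- out[order(-motion)]
    out <- unique(out, by = c("household_id", "timestamp", "sensor_id"))
  }
  out[]
}

# Deterministic household: fixed schedule, optional noise.
quiet_config <- function(onset = 1380, wake = 420, n_days = 40,
                         p_active = 1, p_noise = 0, schedule_sd = 0,
                         away = list(), seed = 1, n_sensors = 6,
                         n_occupants = 1, id = "HH001", ...) {
  household_config(
    household_id = id, n_sensors = n_sensors, n_occupants = n_occupants,
    n_days = n_days, sleep_onset_mean = rep(onset, 7),
    wake_mean = rep(wake, 7), schedule_sd = schedule_sd,
    season_offsets = list(schedule = rep(0, 4), away = rep(0, 4)),
    away_blocks = away, p_active = p_active, p_noise = p_noise,
    seed = seed, ...)
}

# Independent brute-force oracle for the sleep-interval rule: scan every
# maximal inactive run by explicit position-by-position enumeration.
oracle_sleep_interval <- function(pattern) {
  n <- length(pattern)
  best_len <- 0L; best_start <- NA_integer_; best_wake <- NA_integer_
  i <- 1L
  while (i <= n) {
    if (pattern[i] == 0L) {
      j <- i
      while (j < n && pattern[j + 1L] == 0L) j <- j + 1L
      if (j < n) {  # terminated by an activation
        len <- j - i + 1L
        if (len > best_len) {
          best_len <- len; best_start <- i; best_wake <- j + 1L
        }
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (best_len == 0L) return(NULL)
  list(sleep_time = 30 * (best_start - 1L), wake_time = 30 * (best_wake - 1L),
       duration = 30 * best_len)
}

# Raw groups exactly realizing given (n, mean, sd).
realize_group <- function(n, m, s) {
  x <- rnorm(n)
  as.numeric(m + s * scale(x))
}

# Household truth summaries from a generator truth ledger, on the
# 20:00-anchored axis (home time in minutes/day).
truth_summary <- function(truth) {
  nd <- nrow(truth)
  list(
    onset = mean(midnight_to_axis(truth$sleep_onset_min)),
    wake = mean(truth$wake_min) + 240,
    duration = mean(1440 - truth$sleep_onset_min[-nd] + truth$wake_min[-1]),
    home = mean(1440 - (truth$wake_min + 1440 - pmin(truth$sleep_onset_min, 1440)) -
                  truth$away_min))
}
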