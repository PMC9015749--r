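# Synthetic household generator: motion-sensor streams with a known truth
# ledger, emulating the structure of thermostat "donate your data" exports.

#' Configure a synthetic household
#'
#' Describes one simulated household: its sensors, occupants, nightly
#' schedule per weekday, seasonal shifts and daytime away blocks. The
#' generator treats occupants as a single behavioural unit; while the
#' household is home and awake each sensor fires in a 5-minute interval with
#' probability `1 - (1 - p_active)^n_occupants`, and with probability
#' `p_noise` (pets, HVAC drafts) while asleep or away.
#'
#' Schedule conventions: `sleep_onset_mean[w]` is the mean bedtime of the
#' night that *starts* on ISO weekday `w` (1 = Monday), in minutes after
#' midnight of that day; values above 1440 denote falling asleep after
#' midnight. `wake_mean[w]` is the mean wake-up time on mornings whose date
#' has weekday `w`. Onsets are clamped to \[1200, 1635\] (20:00 earliest, a
#' modelling floor matching the sleep-cycle window) and wake times to
#' \[300, 715\].
#'
#' @param household_id character id.
#' @param n_sensors number of motion sensors (>= 1).
#' @param n_occupants number of residents (>= 1).
#' @param n_days days of data to simulate (>= 1).
#' @param start_date first calendar date (`Date`).
#' @param sleep_onset_mean length-7 vector, minutes after midnight, indexed
#'   Monday..Sunday by the evening's weekday.
#' @param wake_mean length-7 vector, minutes after midnight, indexed by the
#'   morning's weekday.
#' @param schedule_sd day-to-day standard deviation of onset and wake
#'   (minutes).
#' @param season_offsets list with numeric length-4 components `schedule`
#'   (added to onset and wake) and `away` (added to away-block durations),
#'   named winter/spring/summer/fall. Dates outside the four season windows
#'   get zero offset.
#' @param away_blocks list of blocks, each a list with `weekdays` (integer
#'   set, ISO), `start` (minutes after midnight), `duration` (minutes) and
#'   `prob` (per-day probability the block occurs).
#' @param p_active per-occupant per-sensor 5-minute activation probability
#'   while home and awake.
#' @param p_noise per-sensor false-activation probability while asleep or
#'   away; must be strictly below `p_active`.
#' @param seed integer RNG seed; identical configs generate identical
#'   streams.
#' @return an object of class `household_config`.
#' @export
household_config <- function(household_id = "HH001",
                             n_sensors = 6L,
                             n_occupants = 2L,
                             n_days = 320L,
                             start_date = as.Date("2018-01-01"),
                             sleep_onset_mean = c(1350, 1350, 1350, 1350, 1380, 1380, 1350),
                             wake_mean = c(390, 390, 390, 390, 390, 435, 435),
                             schedule_sd = 20,
                             season_offsets = list(
                               schedule = c(winter = 0, spring = 0, summer = 0, fall = 0),
                               away     = c(winter = 0, spring = 0, summer = 60, fall = 0)),
                             away_blocks = list(
                               list(weekdays = 1:5, start = 540, duration = 480, prob = 0.9)),
                             p_active = 0.15,
                             p_noise = 0.02,
                             seed = 1L) {
  cfg <- list(household_id = as.character(household_id),
              n_sensors = as.integer(n_sensors),
              n_occupants = as.integer(n_occupants),
              n_days = as.integer(n_days),
              start_date = as.Date(start_date),
              sleep_onset_mean = as.numeric(sleep_onset_mean),
              wake_mean = as.numeric(wake_mean),
              schedule_sd = as.numeric(schedule_sd),
              season_offsets = season_offsets,
              away_blocks = away_blocks,
              p_active = as.numeric(p_active),
              p_noise = as.numeric(p_noise),
              seed = as.integer(seed))
  for (nm in c("schedule", "away")) {
    v <- cfg$season_offsets[[nm]]
    if (!is.null(v) && is.null(names(v)) && length(v) == 4L)
      names(cfg$season_offsets[[nm]]) <- season_levels
  }
  class(cfg) <- "household_config"
  validate_household_config(cfg)
  cfg
}

validate_household_config <- function(cfg) {
  if (!nzchar(cfg$household_id)) stop_config("household_id", "must be non-empty")
  if (is.na(cfg$n_sensors) || cfg$n_sensors < 1L) stop_config("n_sensors", "must be >= 1")
  if (is.na(cfg$n_occupants) || cfg$n_occupants < 1L) stop_config("n_occupants", "must be >= 1")
  if (is.na(cfg$n_days) || cfg$n_days < 1L) stop_config("n_days", "must be >= 1")
  if (is.na(cfg$start_date)) stop_config("start_date", "must be a valid date")
  if (length(cfg$sleep_onset_mean) != 7L || anyNA(cfg$sleep_onset_mean))
    stop_config("sleep_onset_mean", "must hold 7 per-weekday values")
  if (length(cfg$wake_mean) != 7L || anyNA(cfg$wake_mean))
    stop_config("wake_mean", "must hold 7 per-weekday values")
  if (any(cfg$sleep_onset_mean < 1200 | cfg$sleep_onset_mean > 1635))
    stop_config("sleep_onset_mean", "must lie in [1200, 1635] (20:00 to 03:15)")
  if (any(cfg$wake_mean < 300 | cfg$wake_mean > 715))
    stop_config("wake_mean", "must lie in [300, 715] (05:00 to 11:55)")
  if (is.na(cfg$schedule_sd) || cfg$schedule_sd < 0)
    stop_config("schedule_sd", "must be >= 0")
  for (nm in c("schedule", "away")) {
    v <- cfg$season_offsets[[nm]]
    if (is.null(v) || length(v) != 4L || anyNA(v))
      stop_config("season_offsets", sprintf("component '%s' must hold 4 values", nm))
  }
  for (b in cfg$away_blocks) {
    if (is.null(b$weekdays) || is.null(b$start) || is.null(b$duration) || is.null(b$prob))
      stop_config("away_blocks", "entries need weekdays, start, duration, prob")
    if (b$start < 0 || b$start >= 1440) stop_config("away_blocks", "start must be in [0, 1440)")
    if (b$duration < 0) stop_config("away_blocks", "duration must be >= 0")
    if (b$prob < 0 || b$prob > 1) stop_config("away_blocks", "prob must be in [0, 1]")
  }
  if (is.na(cfg$p_active) || cfg$p_active <= 0 || cfg$p_active > 1)
    stop_config("p_active", "must be in (0, 1]")
  if (is.na(cfg$p_noise) || cfg$p_noise < 0 || cfg$p_noise >= cfg$p_active)
    stop_config("p_noise", "must satisfy 0 <= p_noise < p_active")
  if (is.na(cfg$seed)) stop_config("seed", "must be an integer")
  invisible(cfg)
}

season_offset_for <- function(offsets, dates) {
  s <- assign_season(dates)
  out <- offsets[as.character(s)]
  out[is.na(out)] <- 0
  unname(out)
}

#' Generate one household's sensor stream and truth ledger
#'
#' Simulates the full 5-minute grid for every sensor over `n_days`. Each
#' day's bedtime and wake-up time are drawn independently around the
#' weekday- and season-adjusted means; away blocks occur with their
#' configured probability. The returned truth ledger records, for each date,
#' the realized bedtime of the night starting that evening
#' (`sleep_onset_min`, minutes after that date's midnight, possibly > 1440),
#' the wake-up time of that date's own morning (`wake_min`) and the total
#' away minutes that calendar day (`away_min`).
#'
#' @param config a [household_config()].
#' @return object of class `household_stream`: a list with `readings` (a
#'   `data.table` with columns `household_id`, `timestamp` (POSIXct, UTC,
#'   5-minute grid), `sensor_id`, `motion`), `truth` (the ledger) and
#'   `config`.
#' @export
generate_household <- function(config) {
  validate_household_config(config)
  nd <- config$n_days
  ns <- config$n_sensors
  n_int <- nd * 288L
  dates <- config$start_date + 0:(nd - 1L)
  wd <- iso_wday(dates)
  sched_off <- season_offset_for(config$season_offsets$schedule, dates)
  away_off  <- season_offset_for(config$season_offsets$away, dates)
  p_eff <- 1 - (1 - config$p_active)^config$n_occupants

  with_preserved_seed(config$seed, {
    onset <- rnorm(nd, config$sleep_onset_mean[wd] + sched_off, config$schedule_sd)
    onset <- pmin(pmax(onset, 1200), 1635)
    wake  <- rnorm(nd, config$wake_mean[wd] + sched_off, config$schedule_sd)
    wake  <- pmin(pmax(wake, 300), 715)

    total_min <- nd * 1440
    asleep <- logical(n_int)
    mark <- function(state, from, to) {
      # mark 5-min intervals fully inside [from, to) minutes from period start
      from <- max(0, from); to <- min(total_min, to)
      if (to <= from) return(state)
      i0 <- ceiling(from / 5); i1 <- floor(to / 5) - 1
      if (i1 >= i0) state[(i0:i1) + 1L] <- TRUE
      state
    }
    asleep <- mark(asleep, 0, wake[1L])
    for (d in seq_len(nd)) {
      from <- (d - 1L) * 1440 + onset[d]
      to <- if (d < nd) d * 1440 + wake[d + 1L] else total_min
      asleep <- mark(asleep, from, to)
    }

    away <- logical(n_int)
    away_min_day <- numeric(nd)
    for (b in config$away_blocks) {
      hit <- wd %in% b$weekdays & runif(nd) < b$prob
      for (d in which(hit)) {
        dur <- max(0, b$duration + away_off[d])
        from <- (d - 1L) * 1440 + b$start
        to <- min(from + dur, d * 1440)  # away blocks do not cross midnight
        away <- mark(away, from, to)
        away_min_day[d] <- away_min_day[d] + (to - from)
      }
    }

    p <- ifelse(asleep | away, config$p_noise, p_eff)
    motion <- as.integer(runif(n_int * ns) < rep(p, times = ns))

    t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
    ts <- t0 + (0:(n_int - 1L)) * 300
    readings <- data.table::data.table(
      household_id = config$household_id,
      timestamp = rep(ts, times = ns),
      sensor_id = rep(sprintf("S%02d", seq_len(ns)), each = n_int),
      motion = motion)
    truth <- data.table::data.table(
      household_id = config$household_id,
      date = dates,
      sleep_onset_min = onset,
      wake_min = wake,
      away_min = away_min_day)
    structure(list(readings = readings, truth = truth, config = config),
              class = "household_stream")
  })
}

#' @export
print.household_stream <- function(x, ...) {
  cat(sprintf("<household_stream> %s: %d days, %d sensors, %d readings\n",
              x$config$household_id, x$config$n_days, x$config$n_sensors,
              nrow(x$readings)))
  invisible(x)
}

#' Generate a cohort of synthetic households
#'
#' Draws per-household parameters around a template configuration.
#' `heterogeneity` gives the between-household standard deviations:
#' `onset` and `wake` shift the whole weekly schedule of a household by one
#' normal draw each (minutes); `p_active` jitters the activation
#' probability on the log-odds scale. Child seeds are derived
#' deterministically from `seed`.
#'
#' @param n_households number of households (>= 1).
#' @param template a [household_config()] used as the cohort centre.
#' @param heterogeneity named numeric vector/list with any of `onset`,
#'   `wake`, `p_active` (SDs; defaults 0).
#' @param seed master seed.
#' @param materialize if `TRUE` (default) return generated streams; if
#'   `FALSE` return only the per-household configs (memory-friendly for
#'   large cohorts -- call [generate_household()] per config downstream).
#' @return list of `household_stream` objects (or of `household_config`
#'   objects when `materialize = FALSE`).
#' @export
generate_cohort <- function(n_households, template = household_config(),
                            heterogeneity = list(), seed = 1L,
                            materialize = TRUE) {
  if (is.na(n_households) || n_households < 1)
    stop("n_households must be >= 1", call. = FALSE)
  validate_household_config(template)
  het <- function(nm) as.numeric(heterogeneity[[nm]] %||% 0)
  configs <- with_preserved_seed(seed, {
    onset_shift <- rnorm(n_households, 0, het("onset"))
    wake_shift  <- rnorm(n_households, 0, het("wake"))
    logit_jit   <- rnorm(n_households, 0, het("p_active"))
    lapply(seq_len(n_households), function(i) {
      cfg <- template
      cfg$household_id <- sprintf("HH%04d", i)
      cfg$sleep_onset_mean <- pmin(pmax(cfg$sleep_onset_mean + onset_shift[i], 1200), 1635)
      cfg$wake_mean <- pmin(pmax(cfg$wake_mean + wake_shift[i], 300), 715)
      if (het("p_active") > 0) {
        lo <- log(cfg$p_active / (1 - cfg$p_active)) + logit_jit[i]
        cfg$p_active <- max(1 / (1 + exp(-lo)), cfg$p_noise + 1e-6)
      }
      cfg$seed <- derive_seed(seed, i)
      validate_household_config(cfg)
      cfg
    })
  })
  if (!materialize) return(configs)
  lapply(configs, generate_household)
}

#' Read and write the sensor-stream CSV dialect
#'
#' The on-disk dialect has header `household_id,timestamp,sensor_id,motion`
#' with ISO 8601 timestamps on the 5-minute grid and `motion` in \{0, 1\}.
#' The truth ledger is `household_id,date,sleep_onset_min,wake_min,away_min`.
#'
#' @param x a `household_stream`, or a readings/truth `data.table`.
#' @param path file path.
#' @return `read_sensor_csv()` returns a readings `data.table` (timestamps
#'   parsed as UTC POSIXct); the writers return `path` invisibly.
#' @export
write_sensor_csv <- function(x, path) {
  readings <- if (inherits(x, "household_stream")) x$readings else x
  out <- data.table::copy(readings)
  out[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_sensor_csv
#' @export
write_truth_csv <- function(x, path) {
  truth <- if (inherits(x, "household_stream")) x$truth else x
  data.table::fwrite(truth, path)
  invisible(path)
}

#' @rdname write_sensor_csv
#' @export
read_sensor_csv <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "household_id"))
  need <- c("household_id", "timestamp", "sensor_id", "motion")
  if (!all(need %in% names(dt)))
    stop(sprintf("sensor CSV %s lacks columns: %s", path,
                 paste(setdiff(need, names(dt)), collapse = ", ")), call. = FALSE)
  if (!inherits(dt$timestamp, "POSIXct")) {
    ts <- as.POSIXct(gsub("T", " ", as.character(dt$timestamp)), tz = "UTC")
    if (anyNA(ts)) stop(sprintf("unparseable timestamps in %s", path), call. = FALSE)
    dt[, timestamp := ts]
  } else {
    attr(dt$timestamp, "tzone") <- "UTC"
  }
  dt[, sensor_id := as.character(sensor_id)]
  dt[, motion := as.integer(motion)]
  dt[]
}
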