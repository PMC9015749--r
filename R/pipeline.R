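# End-to-end pipeline: cohort -> eligibility -> daily vectors -> cycles ->
# per-stratum clustering -> household indicators -> stratified tests.

utils::globalVariables(c(
  ".", ".I", ".N", "household_id", "date", "slot", "motion", "row",
  "timestamp", "sensor_id", "indicator", "stratum", "value", "display",
  "J", "N", "sleep_time_min", "wake_time_min", "sleep_time_hhmm",
  "wake_time_hhmm"))

#' Run the full indicator pipeline on a cohort
#'
#' For every household: check eligibility (days of data, sensor count,
#' occupants), build binarized daily vectors and sleep cycles, then -- per
#' stratum of the chosen scheme -- cluster the records and extract the
#' cluster-weighted indicators. Sleep time and duration are attributed to
#' the evening date of the cycle and wake-up time to the morning date, so
#' the two sides of a weekend night land on different strata; time at home
#' uses the daily vector's own date. Finally the indicators are compared
#' across strata (Levene, one-way ANOVA and Tukey-Kramer for `weekday` and
#' `season`; additive two-way ANOVA plus cellwise Tukey-Kramer for
#' `season_weekday`; no tests for `"all"`).
#'
#' Every exclusion decision (ineligible household, too few cycles in a
#' stratum, no valid sleep pattern) is recorded in the run log.
#'
#' @param cohort list of `household_stream` and/or `household_config`
#'   objects (configs are generated on the fly and discarded, keeping
#'   memory flat for large cohorts); a single stream is accepted.
#' @param scheme stratification scheme: `"all"`, `"weekday"`, `"season"`,
#'   `"season_weekday"`.
#' @param threshold slot activation threshold (see [binarize()]).
#' @param k_max,min_cycles mixture-fit controls (see
#'   [fit_cycle_clusters()]).
#' @param seed master seed; per-household, per-stratum fit seeds are
#'   derived from it deterministically.
#' @param alpha significance level annotated on the test results.
#' @param min_days,min_sensors,max_occupants eligibility thresholds (see
#'   [check_eligibility()]).
#' @param occupants optional named integer vector of occupant counts,
#'   indexed by household id, for streams lacking a config (e.g. read from
#'   CSV); defaults to 1 occupant when unknown.
#' @param out_dir optional directory; when given, `indicators.csv`,
#'   `anova.csv`, `tukey.csv` and `run_log.csv` are written there.
#' @return list of class `thermosleep_run` with `indicators` (long
#'   `data.table`: household, stratum, indicator, value in minutes --
#'   sleep/wake on the 20:00-anchored axis -- and an hh:mm display column),
#'   `tests` (per-indicator test objects), `log`, and `params`.
#' @export
run_pipeline <- function(cohort,
                         scheme = c("weekday", "season", "season_weekday", "all"),
                         threshold = 4L, k_max = 6L, min_cycles = 10L,
                         seed = 1L, alpha = 0.05,
                         min_days = 300L, min_sensors = 6L, max_occupants = 4L,
                         occupants = NULL, out_dir = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(cohort, c("household_stream", "household_config")))
    cohort <- list(cohort)
  if (length(cohort) == 0L) stop("empty cohort", call. = FALSE)

  log_rows <- list()
  ind_rows <- list()
  note <- function(hh, stage, stratum, decision, reason) {
    log_rows[[length(log_rows) + 1L]] <<- data.table::data.table(
      household_id = hh, stage = stage, stratum = stratum,
      decision = decision, reason = reason)
  }

  for (i in seq_along(cohort)) {
    item <- cohort[[i]]
    stream <- if (inherits(item, "household_config")) generate_household(item) else item
    if (!inherits(stream, "household_stream") && !is.list(stream))
      stop("cohort entries must be household_stream or household_config objects",
           call. = FALSE)
    readings <- stream$readings
    hh <- as.character(readings$household_id[1L])
    n_occ <- if (!is.null(stream$config)) stream$config$n_occupants
             else as.integer(occupants[hh] %||% NA_integer_)
    if (is.na(n_occ)) n_occ <- 1L
    days_avail <- length(unique(ts_date(readings$timestamp)))
    n_sens <- length(unique(readings$sensor_id))
    if (!check_eligibility(days_avail, n_sens, n_occ, min_days = min_days,
                           min_sensors = min_sensors,
                           max_occupants = max_occupants)) {
      note(hh, "eligibility", NA_character_, "excluded",
           sprintf("ineligible (days=%d, sensors=%d, occupants=%d)",
                   days_avail, n_sens, n_occ))
      next
    }
    note(hh, "eligibility", NA_character_, "included", NA_character_)

    daily <- build_daily_vectors(readings, threshold = threshold)
    cycles <- build_sleep_cycles(daily)

    add_ind <- function(stratum, indicator, value, kk, nn) {
      ind_rows[[length(ind_rows) + 1L]] <<- data.table::data.table(
        household_id = hh, scheme = scheme, stratum = stratum,
        indicator = indicator, value = value, k = kk, n_records = nn)
    }

    # sleep-side indicators: strata by attribution date
    for (side in c("onset", "wake")) {
      dates <- if (side == "onset") cycles$index$cycle_date
               else attribute_cycle(cycles$index$cycle_date, "wake_time")
      parts <- partition_dates(dates, scheme)
      for (s in seq_along(parts)) {
        lev <- names(parts)[s]
        X <- cycles$cycles[parts[[s]], , drop = FALSE]
        fit_seed <- derive_seed(seed, i * 67L + s * (if (side == "onset") 1L else 2L))
        res <- household_sleep_indicators(X, k_max = k_max, seed = fit_seed,
                                          min_records = min_cycles)
        if (is_excluded(res)) {
          note(hh, paste0("sleep_", side), lev, "excluded", exclusion_reason(res))
          next
        }
        if (side == "onset") {
          add_ind(lev, "sleep_time", res$sleep_time, attr(res, "k"), attr(res, "n_cycles"))
          add_ind(lev, "duration", res$duration, attr(res, "k"), attr(res, "n_cycles"))
        } else {
          add_ind(lev, "wake_time", res$wake_time, attr(res, "k"), attr(res, "n_cycles"))
        }
      }
    }

    # time at home: strata by the day's own date
    parts <- partition_dates(daily$index$date, scheme)
    for (s in seq_along(parts)) {
      lev <- names(parts)[s]
      X <- daily$slots[parts[[s]], , drop = FALSE]
      res <- household_home_time(X, k_max = k_max,
                                 seed = derive_seed(seed, i * 67L + s * 3L),
                                 min_records = min_cycles)
      if (is_excluded(res)) {
        note(hh, "home_time", lev, "excluded", exclusion_reason(res))
        next
      }
      add_ind(lev, "home_time", as.numeric(res), attr(res, "k"), attr(res, "n_days"))
    }
  }

  indicators <- data.table::rbindlist(ind_rows)
  run_log <- data.table::rbindlist(log_rows)
  if (nrow(indicators) == 0L)
    stop("empty cohort: no household produced any indicator", call. = FALSE)

  tests <- list()
  if (scheme != "all") {
    for (ind in unique(indicators$indicator)) {
      d <- indicators[indicator == ind]
      counts <- table(d$stratum)
      if (length(counts) < 2L || any(counts < 2L)) next  # too few households per stratum
      tests[[ind]] <- if (scheme == "season_weekday") {
        sw <- split_season_weekday(d$stratum)
        two <- anova_twoway_additive(d$value, sw$season, sw$weekday)
        two$term <- c("season", "weekday")
        list(anova = two,
             tukey = tukey_kramer(values = d$value, groups = d$stratum))
      } else {
        a <- anova_oneway(d$value, d$stratum)
        list(levene = levene_test(d$value, d$stratum),
             anova = a,
             # degenerate zero within-group variance: no error term to
             # studentize against, post hoc skipped
             tukey = if (a$ms_within > 0)
               tukey_kramer(values = d$value, groups = d$stratum,
                            ms_within = a$ms_within,
                            df_within = a$df_within),
             significant = a$p < alpha)
      }
    }
  }

  out <- structure(list(indicators = indicators, tests = tests, log = run_log,
                        params = list(scheme = scheme, threshold = threshold,
                                      k_max = k_max, min_cycles = min_cycles,
                                      seed = seed, alpha = alpha)),
                   class = "thermosleep_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.thermosleep_run <- function(x, ...) {
  cat(sprintf("<thermosleep_run> scheme = %s: %d indicator values, %d households\n",
              x$params$scheme, nrow(x$indicators),
              length(unique(x$indicators$household_id))))
  for (ind in names(x$tests)) {
    a <- x$tests[[ind]]$anova
    if (inherits(a, "anova_oneway"))
      cat(sprintf("  %-11s F = %.2f, p = %.3g\n", ind, a$F, a$p))
  }
  invisible(x)
}

#' Write pipeline outputs as CSV
#'
#' Emits `indicators.csv` (wide per household-stratum, with 20:00-axis
#' minutes and hh:mm display columns), `anova.csv`, `tukey.csv` and
#' `run_log.csv` into `dir`.
#'
#' @param run a `thermosleep_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "thermosleep_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wide <- data.table::dcast(run$indicators,
                            household_id + scheme + stratum ~ indicator,
                            value.var = "value")
  for (col in c("sleep_time", "wake_time", "duration", "home_time"))
    if (!col %in% names(wide)) wide[, (col) := NA_real_]
  data.table::setnames(wide,
    c("sleep_time", "wake_time", "duration", "home_time"),
    c("sleep_time_min", "wake_time_min", "duration_min", "minutes_at_home"))
  wide[, sleep_time_hhmm := format_hhmm(axis_to_midnight(sleep_time_min))]
  wide[, wake_time_hhmm := format_hhmm(axis_to_midnight(wake_time_min))]
  data.table::fwrite(wide, file.path(dir, "indicators.csv"))

  anova_rows <- list()
  tukey_rows <- list()
  for (ind in names(run$tests)) {
    t <- run$tests[[ind]]
    a <- t$anova
    if (inherits(a, "anova_oneway")) {
      anova_rows[[ind]] <- data.table::data.table(
        indicator = ind, term = "stratum", ss = a$ss_between, df = a$df_between,
        F = a$F, p = a$p, ss_residual = a$ss_within, df_residual = a$df_within)
    } else {
      anova_rows[[ind]] <- data.table::data.table(
        indicator = ind, term = a$term, ss = a$ss, df = a$df, F = a$F, p = a$p,
        ss_residual = attr(a, "ss_residual"), df_residual = attr(a, "df_residual"))
    }
    if (!is.null(t$tukey)) {
      tk <- data.table::as.data.table(as.data.frame(t$tukey))
      tk[, indicator := ind]
      tukey_rows[[ind]] <- tk
    }
  }
  if (length(anova_rows))
    data.table::fwrite(data.table::rbindlist(anova_rows), file.path(dir, "anova.csv"))
  if (length(tukey_rows))
    data.table::fwrite(data.table::rbindlist(tukey_rows, use.names = TRUE),
                       file.path(dir, "tukey.csv"))
  data.table::fwrite(run$log, file.path(dir, "run_log.csv"))
  invisible(dir)
}
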