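# Published cohort descriptive statistics, shipped as plain CSV. These are
# the per-stratum (n, mean, SD) summaries reported for the 481-household
# 2018 ecobee Donate Your Data cohort; the raw data are proprietary, but
# the summary-statistics ANOVA / Tukey-Kramer layer reproduces the
# published F and q values from these tables alone.

#' Published DYD cohort summary tables
#'
#' Per-stratum descriptive statistics (sample size, mean, SD in minutes) of
#' the four indicators -- `sleep_time`, `wake_time`, `duration`,
#' `home_time` -- for the season- and weekday-stratified 2018 Donate Your
#' Data thermostat cohort of 481 eligible North American households.
#' Clock-valued means (sleep and wake-up time) are given in minutes after
#' midnight (e.g. 1352 = 22:32, 382 = 06:22); SDs are always minutes.
#'
#' @param scale `"season"` or `"weekday"`.
#' @param indicator optional filter: one of `"sleep_time"`, `"wake_time"`,
#'   `"duration"`, `"home_time"`.
#' @return data.frame with columns `indicator`, `label`, `n`, `mean`, `sd`.
#' @export
dyd_summary_tables <- function(scale = c("season", "weekday"),
                               indicator = NULL) {
  scale <- match.arg(scale)
  path <- system.file("extdata", sprintf("dyd_%s_summary.csv", scale),
                      package = "thermosleep", mustWork = TRUE)
  out <- as.data.frame(data.table::fread(path))
  if (!is.null(indicator)) {
    indicator <- match.arg(indicator,
                           c("sleep_time", "wake_time", "duration", "home_time"))
    out <- out[out$indicator == indicator, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
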