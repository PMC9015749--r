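# thermosleep

Household sleep and home-occupancy indicators from smart-thermostat motion
sensors.

Smart thermostats with remote motion sensors (e.g. those behind ecobee's
*Donate Your Data* programme) record, every 5 minutes, whether each sensor
detected movement. For population-health surveillance this passive signal
can stand in for self-reported sleep diaries: the nightly quiet block marks
sleep, its boundaries mark bed- and wake-time, and daytime activity marks
time spent at home. `thermosleep` implements the full estimation chain and
the inferential layer used to compare the indicators across weekdays,
seasons, and season×weekday cells — plus a synthetic household generator
with a known truth ledger, so the pipeline is testable without any
proprietary data.

## Method at a glance

For a household-day, sensor activations are summed per half-hour slot and
binarized: slot *i* is active iff

    score_i = Σ_sensors Σ_{5-min intervals in slot i} 1{motion} ≥ 4.

Consecutive days are spliced into 32-slot *sleep cycles* (20:00 → noon).
A household's cycles are segmented with a diagonal-covariance Gaussian
mixture (BIC-selected k ≤ 6); each cluster's mean activation is thresholded
at > 0.5 into a binary pattern, and the longest inactive run terminated by
an activation gives sleep time *s*, wake time *w*, duration *w − s*.
Household indicators are cluster-weight averages, the weight being the
assigned fraction of records. Daily time at home is 30 min × (active
pattern slots). Strata are compared with Levene's test, one-way ANOVA and
Tukey–Kramer post hoc comparisons (q = |m₁−m₂| / √((MS_w/2)(1/n₁+1/n₂))),
or an additive two-way ANOVA with Type II SS for season×weekday — all
available both from raw values and from printed (n, mean, SD) summaries.

## Worked example

Re-analysing the published seasonal time-at-home summaries (shipped with
the package; means/SDs in minutes):

```r
library(thermosleep)
home <- dyd_summary_tables("season", indicator = "home_time")
anova_oneway_from_summary(home)
#> One-way ANOVA
#>   between: SS = 8.744e+05, df = 3
#>   within:  SS = 9.879e+07, df = 1839
#>   F = 5.4258, p = 0.001027
tukey_kramer(summaries = home)
#> Tukey-Kramer comparisons (MS_within = 5.372e+04, df = 1839)
#>  group1 group2   diff    se      q  ci_low ci_high     p_adj
#>  spring summer  36.55 10.83 3.3749  -2.833  75.933 0.0800317
#>  spring   fall  -6.26 10.79 0.5799 -45.514  32.994 0.9767297
#>  spring winter -23.30 10.77 2.1643 -62.449  15.849 0.4194195
#>  summer   fall -42.81 10.83 3.9529 -82.193  -3.427 0.0268978
#>  summer winter -59.85 10.80 5.5411 -99.128 -20.572 0.0005358
#>    fall winter -17.04 10.77 1.5828 -56.189  22.109 0.6776990
```

Households spend significantly more time at home in winter than in summer
(59.85 min/day more, q = 5.54, adjusted p < .001) — about one extra hour
indoors per day — and more in fall than summer (42.81 min, q = 3.95).
The sample-wide weekday wake-up average:

```r
format_hhmm(grand_weighted_mean(dyd_summary_tables("weekday",
                                                   indicator = "wake_time")))
#> [1] "06:20"
```

And a synthetic household end to end (defaults: 6 sensors, 2 occupants,
320 days, weekend bedtime 30 min later, Mon–Fri 9–5 away block):

```r
cfg <- household_config(seed = 7)
st  <- generate_household(cfg)
st
#> <household_stream> HH001: 320 days, 6 sensors, 552960 readings
cyc <- build_sleep_cycles(build_daily_vectors(st$readings))
household_sleep_indicators(cyc, seed = 1)
#> <sleep_indicators> sleep 22:41, wake 06:41, duration 480 min
```

The recovered bedtime (22:41) is the cluster-weighted mix of the 22:30
weeknight and 23:00 weekend schedules. The full stratified pipeline —
eligibility filter (≥ 300 days, ≥ 6 sensors, ≤ 4 occupants), per-stratum
clustering, ANOVA/Tukey tables, run log — is one call:

```r
run <- run_pipeline(generate_cohort(20, cfg, heterogeneity = list(onset = 30),
                                    materialize = FALSE),
                    scheme = "weekday", seed = 1, out_dir = "out/")
```

A command-line interface with `simulate` / `run` subcommands is installed
at `inst/cli/thermosleep.R`.

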