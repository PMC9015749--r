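test_that("slot scores count (sensor x 5-minute) activations", {
  # one sensor active 4 consecutive intervals in slot 10 (05:00-05:30)
  r1 <- make_readings(active = list(list(sensor = "S01",
                                         minutes = c(300, 305, 310, 315))))
  s1 <- aggregate_to_slots(r1)
  expect_equal(s1[11], 4L)
  expect_equal(sum(s1), 4L)
  # 4 sensors each active for one interval in the same slot
  r2 <- make_readings(active = lapply(1:4, function(i)
    list(sensor = sprintf("S%02d", i), minutes = 300 + 5 * (i - 1))))
  expect_equal(aggregate_to_slots(r2)[11], 4L)
  # no activations
  expect_equal(aggregate_to_slots(make_readings(fill_grid = TRUE)), integer(48))
})

test_that("aggregation is invariant to reading order and matches a brute-force scan", {
  st <- generate_household(quiet_config(n_days = 3, n_sensors = 3,
                                        p_active = 0.4, p_noise = 0.05,
                                        seed = 21))
  r <- st$readings
  shuffled <- r[sample(nrow(r))]
  daily <- build_daily_vectors(r)
  daily2 <- build_daily_vectors(shuffled)
  expect_equal(daily2$scores[order(daily2$index$date), ],
               daily$scores[order(daily$index$date), ])

  # brute-force oracle: count motion per slot, day by day
  minute <- (as.numeric(r$timestamp) %/% 60) %% 1440
  day <- as.Date(floor(as.numeric(r$timestamp) / 86400), origin = "1970-01-01")
  for (d in sort(unique(day))) {
    expected <- integer(48)
    sel <- which(day == d & r$motion == 1L)
    for (i in sel) {
      slot <- minute[i] %/% 30
      expected[slot + 1L] <- expected[slot + 1L] + 1L
    }
    row <- which(daily$index$date == d)
    expect_equal(daily$scores[row, ], expected)
  }
})

test_that("binarization applies the score threshold", {
  expect_equal(binarize(c(0L, 3L, 4L, 5L, 36L)), c(0L, 0L, 1L, 1L, 1L))
  expect_equal(binarize(rep(0L, 48)), rep(0L, 48))
  expect_equal(binarize(c(1L, 2L, 3L), threshold = 2L), c(0L, 1L, 1L))
  expect_error(binarize(c(1L, -1L)), "negative")
})

test_that("off-grid and duplicate readings are rejected", {
  bad <- make_readings(active = list(list(sensor = "S01", minutes = 5)))
  bad$timestamp <- bad$timestamp + 1  # 1 second off the grid
  expect_error(aggregate_to_slots(bad), "off-grid")
  dup <- make_readings(active = list(list(sensor = "S01", minutes = c(300, 300))))
  expect_error(aggregate_to_slots(dup), "duplicate")
})

test_that("eligibility enforces the 300-day / 6-sensor / 4-occupant thresholds", {
  expect_true(check_eligibility(300, 6, 4))
  expect_false(check_eligibility(299, 6, 4))
  expect_false(check_eligibility(300, 5, 4))
  expect_false(check_eligibility(300, 6, 5))
  expect_equal(check_eligibility(c(300, 299), c(6, 6), c(4, 4)),
               c(TRUE, FALSE))
  expect_error(check_eligibility(-1, 6, 4), "non-negative")
})

test_that("sleep cycles splice consecutive days and skip gaps", {
  st <- generate_household(quiet_config(n_days = 301, n_sensors = 1,
                                        p_active = 0.9, seed = 4))
  daily <- build_daily_vectors(st$readings)
  cyc <- build_sleep_cycles(daily)
  expect_equal(nrow(cyc$index), 300L)  # n - 1 consecutive pairs
  expect_equal(cyc$n_gaps, 0L)
  # definitional concatenation: day-d slots 40..47 ++ day-(d+1) slots 0..23
  i0 <- which(daily$index$date == cyc$index$cycle_date[5])
  i1 <- which(daily$index$date == cyc$index$cycle_date[5] + 1)
  expect_equal(cyc$cycles[5, ], c(daily$slots[i0, 41:48], daily$slots[i1, 1:24]))

  # remove the middle day: d and d+2 alone form no cycle
  keep <- daily$index$date != daily$index$date[2]
  gap <- structure(list(index = daily$index[which(keep)],
                        scores = daily$scores[keep, ],
                        slots = daily$slots[keep, ],
                        threshold = 4L), class = "daily_activity")
  cyc2 <- build_sleep_cycles(gap)
  expect_equal(nrow(cyc2$index), 298L)
  expect_equal(cyc2$n_gaps, 1L)
})

test_that("daily and cycle CSV writers emit the documented layouts", {
  st <- generate_household(quiet_config(n_days = 3, n_sensors = 2,
                                        p_active = 0.8, seed = 2))
  daily <- build_daily_vectors(st$readings)
  cyc <- build_sleep_cycles(daily)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_daily_csv(daily, f1)
  write_cycle_csv(cyc, f2)
  expect_match(readLines(f1, n = 1), "^household_id,date,s00,")
  expect_match(readLines(f2, n = 1), "^household_id,cycle_date,c00,")
  expect_equal(nrow(data.table::fread(f1)), 3L)
  expect_equal(nrow(data.table::fread(f2)), 2L)
})
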