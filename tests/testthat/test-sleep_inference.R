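pattern_of <- function(inactive0) {
  # 32-slot pattern with the given 0-indexed slots inactive
  p <- rep(1L, 32)
  p[inactive0 + 1L] <- 0L
  p
}

test_that("mixture selects k = 1 for identical cycles and recovers archetypes", {
  v <- pattern_of(6:21)
  X <- matrix(rep(v, 20), nrow = 20, byrow = TRUE)
  m <- fit_cycle_clusters(X, seed = 1)
  expect_s3_class(m, "activity_gmm")
  expect_equal(m$k, 1L)
  expect_equal(extract_pattern(X)$slots, v)

  # two well-separated archetypes, 50/50: k = 2 and assignments reproduce labels
  a <- pattern_of(4:17)   # early sleeper
  b <- pattern_of(12:27)  # late sleeper
  X2 <- rbind(matrix(rep(a, 30), 30, byrow = TRUE),
              matrix(rep(b, 30), 30, byrow = TRUE))
  labels <- rep(1:2, each = 30)
  m2 <- fit_cycle_clusters(X2, seed = 3)
  expect_equal(m2$k, 2L)
  expect_equal(length(unique(m2$assign[labels == 1])), 1L)
  expect_equal(length(unique(m2$assign[labels == 2])), 1L)
  expect_false(m2$assign[1] == m2$assign[60])
  expect_equal(sort(m2$prop), c(0.5, 0.5))

  # seed contract
  m3 <- fit_cycle_clusters(X2, seed = 3)
  expect_identical(m2$assign, m3$assign)
  expect_equal(m2$loglik, m3$loglik)

  # too few records: signaled exclusion, not an error
  few <- fit_cycle_clusters(X2[1:5, ], min_records = 10)
  expect_true(is_excluded(few))
})

test_that("patterns threshold mean activation strictly above 0.5", {
  m3 <- rbind(pattern_of(10:15), pattern_of(10:15), pattern_of(c(10:15, 20)))
  p <- extract_pattern(m3)
  expect_equal(p$slots[21], 1L)       # mean 2/3 > 0.5 -> active
  m2 <- rbind(pattern_of(10:15), pattern_of(c(10:15, 20)))
  expect_equal(extract_pattern(m2)$slots[21], 0L)  # mean exactly 0.5 -> inactive
  single <- matrix(pattern_of(3:9), nrow = 1)
  expect_equal(extract_pattern(single)$slots, pattern_of(3:9))
  expect_equal(extract_pattern(m3, n_total = 30)$weight, 0.1)
})

test_that("sleep-interval detection follows the largest terminated inactive run", {
  # slots 0-5 active, 6-21 inactive, 22-31 active
  r <- detect_sleep_interval(pattern_of(6:21))
  expect_equal(r$sleep_time, 180)
  expect_equal(r$wake_time, 660)
  expect_equal(r$duration, 480)
  # two runs, lengths 3 and 5: the longer wins
  r2 <- detect_sleep_interval(pattern_of(c(2:4, 10:14)))
  expect_equal(r2$sleep_time, 300)
  expect_equal(r2$wake_time, 450)
  expect_equal(r2$duration, 150)
  # equal lengths: earliest start wins
  r3 <- detect_sleep_interval(pattern_of(c(2:4, 10:12)))
  expect_equal(r3$sleep_time, 60)
  # run starting at slot 0 is allowed (sleep at 20:00)
  r4 <- detect_sleep_interval(pattern_of(0:15))
  expect_equal(r4$sleep_time, 0)
  expect_equal(r4$duration, 480)
  # degenerate patterns: all active / all inactive / unterminated trailing run
  expect_true(is_excluded(detect_sleep_interval(rep(1L, 32))))
  expect_true(is_excluded(detect_sleep_interval(rep(0L, 32))))
  expect_true(is_excluded(detect_sleep_interval(pattern_of(20:31))))
  expect_error(detect_sleep_interval(rep(0L, 31)), "32")
})

test_that("detection agrees with the brute-force run oracle on random patterns", {
  set.seed(404)
  n_checked <- 0L
  mismatches <- 0L
  for (p_active in c(0.2, 0.5, 0.8)) {
    pats <- matrix(as.integer(runif(20000 * 32) < p_active), ncol = 32)
    for (i in seq_len(nrow(pats))) {
      got <- detect_sleep_interval(pats[i, ])
      want <- oracle_sleep_interval(pats[i, ])
      ok <- if (is.null(want)) {
        is_excluded(got)
      } else {
        !is_excluded(got) &&
          got$sleep_time == want$sleep_time &&
          got$wake_time == want$wake_time &&
          got$duration == want$duration &&
          got$duration == got$wake_time - got$sleep_time
      }
      if (!ok) mismatches <- mismatches + 1L
      n_checked <- n_checked + 1L
    }
  }
  expect_equal(n_checked, 60000L)
  expect_equal(mismatches, 0L)
})

test_that("weighted indicators average valid patterns by renormalized weight", {
  mk <- function(inactive0, w) {
    p <- extract_pattern(matrix(pattern_of(inactive0), nrow = 1))
    p$weight <- w
    p
  }
  two <- weighted_indicators(list(mk(6:21, 0.6), mk(4:19, 0.4)))
  expect_equal(two$sleep_time, 0.6 * 180 + 0.4 * 120)  # 156 = 22:36
  three <- weighted_indicators(list(mk(6:21, 0.5), mk(7:21, 0.3), mk(8:21, 0.2)))
  expect_equal(three$duration, 0.5 * 480 + 0.3 * 450 + 0.2 * 420)  # 465
  one <- weighted_indicators(list(mk(6:21, 1)))
  expect_equal(one$wake_time, 660)
  # invalid pattern dropped, weights renormalized
  allact <- mk(integer(0), 0.5)
  mixed <- weighted_indicators(list(allact, mk(6:21, 0.5)))
  expect_equal(mixed$sleep_time, 180)
  expect_true(is_excluded(weighted_indicators(list(allact))))
})

test_that("noiseless household recovers its schedule exactly through the pipeline", {
  cfg <- quiet_config(onset = 1380, wake = 420, n_days = 40, seed = 8)
  st <- generate_household(cfg)
  cyc <- build_sleep_cycles(build_daily_vectors(st$readings))
  res <- household_sleep_indicators(cyc, seed = 1)
  expect_equal(res$sleep_time, 180)
  expect_equal(res$wake_time, 660)
  expect_equal(res$duration, 480)
  expect_equal(attr(res, "k"), 1L)
})
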