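test_that("Levene statistic matches the textbook fixture and its invariances", {
  g1 <- c(12, 15, 11, 19, 14)
  g2 <- c(22, 18, 25, 17, 24)
  vals <- c(g1, g2)
  grp <- rep(c("a", "b"), each = 5)
  lv <- levene_test(vals, grp)
  # frozen independent oracle (scipy.stats.levene, center='mean')
  expect_equal(lv$W, 0.5007727975270483, tolerance = 1e-10)
  expect_equal(lv$p, 0.49925436767134024, tolerance = 1e-8)
  bf <- levene_test(vals, grp, center = "median")
  expect_equal(bf$W, 0.24324324324324298, tolerance = 1e-10)
  expect_equal(bf$p, 0.6351256321864707, tolerance = 1e-8)
  # location invariance: shifting one group leaves W unchanged
  shifted <- levene_test(c(g1 + 100, g2), grp)
  expect_equal(shifted$W, lv$W, tolerance = 1e-12)
  # identical groups: zero spread of deviations
  same <- levene_test(c(g1, g1), grp)
  expect_equal(same$W, 0)
  expect_equal(same$p, 1)
})

test_that("one-way ANOVA: F identities and unit invariance", {
  set.seed(31)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  vals <- c(x, y); grp <- rep(c("x", "y"), c(40, 35))
  a <- anova_oneway(vals, grp)
  # two-group F equals the squared pooled-variance t statistic
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(a$p, tt$p.value, tolerance = 1e-12)
  # unit change: F invariant, SS scale with the square
  a60 <- anova_oneway(vals / 60, grp)
  expect_equal(a60$F, a$F, tolerance = 1e-12)
  expect_equal(a60$ss_between, a$ss_between / 3600, tolerance = 1e-12)
  # equal group means -> F = 0
  z <- c(1, 2, 3, 1, 2, 3)
  expect_equal(anova_oneway(z, rep(c("a", "b"), each = 3))$F, 0)
})

test_that("summary-based ANOVA equals raw ANOVA on realizing groups", {
  set.seed(5)
  spec <- data.frame(label = c("w", "x", "y", "z"),
                     n = c(45, 52, 38, 61),
                     mean = c(510, 498, 530, 487),
                     sd = c(210, 195, 225, 205))
  raw <- lapply(seq_len(nrow(spec)),
                function(i) realize_group(spec$n[i], spec$mean[i], spec$sd[i]))
  vals <- unlist(raw)
  grp <- rep(spec$label, spec$n)
  a_raw <- anova_oneway(vals, grp)
  a_sum <- anova_oneway_from_summary(spec)
  expect_equal(a_sum$F, a_raw$F, tolerance = 1e-9)
  expect_equal(a_sum$ss_between, a_raw$ss_between, tolerance = 1e-9)
  expect_equal(a_sum$ss_within, a_raw$ss_within, tolerance = 1e-9)
  expect_equal(a_sum$df_within, a_raw$df_within)
  expect_error(anova_oneway_from_summary(data.frame(n = c(1, 5), mean = 0, sd = 1)),
               "n >= 2")
  expect_equal(anova_oneway_from_summary(
    data.frame(n = c(10, 10), mean = c(5, 5), sd = c(2, 2)))$F, 0)
})

test_that("additive two-way ANOVA gives Type II SS (balanced and unbalanced)", {
  set.seed(77)
  # balanced: Type II coincides with sequential Type I
  ab <- expand.grid(a = c("a1", "a2", "a3"), b = c("b1", "b2"),
                    rep = 1:6, stringsAsFactors = FALSE)
  y <- rnorm(nrow(ab)) + (ab$a == "a2") * 0.8 + (ab$b == "b2") * 0.5
  two <- anova_twoway_additive(y, ab$a, ab$b)
  seq1 <- anova(lm(y ~ factor(ab$a) + factor(ab$b)))
  expect_equal(two$ss, seq1$`Sum Sq`[1:2], tolerance = 1e-10)
  expect_equal(two$df, seq1$Df[1:2])
  expect_equal(attr(two, "df_residual"), nrow(ab) - 2 - 1 - 1)

  # unbalanced fixture vs a normal-equations projection oracle
  a <- c("a1", "a1", "a1", "a2", "a2", "a2", "a2", "a3", "a3", "a1", "a2", "a3")
  b <- c("b1", "b2", "b1", "b1", "b2", "b2", "b2", "b1", "b2", "b2", "b1", "b1")
  y2 <- c(3.1, 4.0, 2.9, 5.2, 6.1, 5.8, 6.4, 1.9, 3.3, 4.4, 5.0, 2.2)
  two2 <- anova_twoway_additive(y2, a, b)
  rss_of <- function(form_x) {
    X <- stats::model.matrix(form_x)
    beta <- solve(crossprod(X), crossprod(X, y2))
    sum((y2 - X %*% beta)^2)
  }
  r_full <- rss_of(~ factor(a) + factor(b))
  expect_equal(two2$ss[1], rss_of(~ factor(b)) - r_full, tolerance = 1e-10)
  expect_equal(two2$ss[2], rss_of(~ factor(a)) - r_full, tolerance = 1e-10)
  expect_equal(attr(two2, "ss_residual"), r_full, tolerance = 1e-10)
  expect_equal(attr(two2, "df_residual"), 12L - 2L - 1L - 1L)
})

test_that("Tukey-Kramer reproduces the frozen fixture and its identities", {
  av <- c(3.1, 2.8, 3.6, 3.3, 2.9)
  bv <- c(4.0, 4.4, 3.9, 4.6)
  cv <- c(2.5, 2.9, 2.2, 2.8, 2.6, 2.4)
  vals <- c(av, bv, cv)
  grp <- rep(c("a", "b", "c"), c(5, 4, 6))
  tk <- tukey_kramer(values = vals, groups = grp)
  expect_equal(attr(tk, "ms_within"), 0.08940277777777776, tolerance = 1e-12)
  expect_equal(attr(tk, "df_within"), 12L)
  ab <- tk[tk$group1 == "a" & tk$group2 == "b", ]
  # frozen oracle: scipy studentized_range
  expect_equal(ab$diff, -1.085, tolerance = 1e-12)
  expect_equal(ab$se, 0.14182956320880355, tolerance = 1e-10)
  expect_equal(ab$q, 7.650027084992476, tolerance = 1e-8)
  expect_equal(ab$p_adj, 0.00042809251409892113, tolerance = 1e-6)
  ac <- tk[tk$group1 == "a" & tk$group2 == "c", ]
  expect_equal(ac$q, 4.478277159454244, tolerance = 1e-8)
  expect_equal(ac$p_adj, 0.020562849033095132, tolerance = 1e-6)
  # q symmetric in the pair; CI symmetric about diff
  expect_equal(abs(ab$diff) / ab$se, ab$q)
  expect_equal((ab$ci_low + ab$ci_high) / 2, ab$diff, tolerance = 1e-12)
  # p_adj monotone decreasing in q across pairs
  ord <- order(tk$q)
  expect_true(all(diff(tk$p_adj[ord]) <= 1e-12))
  # equal means -> q = 0, p = 1
  eq <- tukey_kramer(values = rep(c(1, 2, 3), 2),
                     groups = rep(c("u", "v"), each = 3))
  expect_equal(eq$q, 0)
  expect_equal(eq$p_adj, 1)
  # equal-n reduction to sqrt(ms/n)
  tkeq <- tukey_kramer(summaries = data.frame(label = c("p", "q"),
                                              n = c(10, 10),
                                              mean = c(0, 1), sd = c(1, 1)))
  expect_equal(tkeq$se, sqrt(attr(tkeq, "ms_within") / 10), tolerance = 1e-12)
})

test_that("grand weighted mean pools group summaries by sample size", {
  expect_equal(grand_weighted_mean(data.frame(n = c(1, 3), mean = c(0, 4))), 3)
  expect_equal(grand_weighted_mean(data.frame(n = 7, mean = 5.5)), 5.5)
})

test_that("published summary tables load with the documented layout", {
  season <- dyd_summary_tables("season")
  expect_equal(nrow(season), 16L)
  expect_equal(names(season), c("indicator", "label", "n", "mean", "sd"))
  home <- dyd_summary_tables("season", indicator = "home_time")
  expect_equal(nrow(home), 4L)
  weekday <- dyd_summary_tables("weekday")
  expect_equal(nrow(weekday), 28L)
  expect_equal(sum(weekday$indicator == "wake_time"), 7L)
})

test_that("one-way ANOVA holds its nominal type-I error (quick calibration)", {
  set.seed(606)
  reps <- 1000
  grp <- rep(c("a", "b", "c", "d"), each = 25)
  hits <- 0L
  for (r in seq_len(reps)) {
    p <- anova_oneway(rnorm(100), grp)$p
    if (p < 0.05) hits <- hits + 1L
  }
  rate <- hits / reps
  se3 <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_gt(rate, 0.05 - se3)
  expect_lt(rate, 0.05 + se3)
})
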