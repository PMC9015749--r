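# Inferential layer: Levene's test, one- and two-way ANOVA, Tukey-Kramer
# post hoc comparisons. Every test also runs from (n, mean, SD) group
# summaries, which is how published descriptive tables are re-analysed
# without the raw per-household data.

as_groups <- function(values, groups) {
  f <- droplevels(factor(groups))
  keep <- !is.na(values) & !is.na(f)
  split(values[keep], droplevels(f[keep]))
}

check_groups <- function(g, min_k = 2L, min_n = 2L) {
  if (length(g) < min_k)
    stop(sprintf("need at least %d groups", min_k), call. = FALSE)
  if (any(vapply(g, length, integer(1)) < min_n))
    stop(sprintf("every group needs at least %d observations", min_n), call. = FALSE)
  g
}

#' Levene's test for homogeneity of variance
#'
#' Classic Levene statistic: a one-way ANOVA F on the absolute deviations
#' of each observation from its group centre. The centre is the group mean
#' (Levene's original form, the default) or the group median
#' (Brown-Forsythe).
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor).
#' @param center `"mean"` or `"median"`.
#' @return list of class `levene_test` with `W`, `p`, `df` (c(k-1, N-k)).
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- check_groups(as_groups(values, groups))
  centre_fun <- if (center == "mean") mean else stats::median
  z <- lapply(g, function(x) abs(x - centre_fun(x)))
  a <- anova_oneway(unlist(z, use.names = FALSE),
                    rep(names(g), vapply(z, length, integer(1))))
  structure(list(W = a$F, p = a$p, df = c(a$df_between, a$df_within),
                 center = center),
            class = "levene_test")
}

#' @export
print.levene_test <- function(x, ...) {
  cat(sprintf("Levene test (center = %s): W = %.4f on (%d, %d) df, p = %.4g\n",
              x$center, x$W, x$df[1], x$df[2], x$p))
  invisible(x)
}

new_anova_oneway <- function(ssb, ssw, dfb, dfw, summaries) {
  msb <- ssb / dfb
  msw <- ssw / dfw
  F <- if (msw > 0) msb / msw else ifelse(msb > 0, Inf, 0)
  structure(list(ss_between = ssb, ss_within = ssw,
                 df_between = dfb, df_within = dfw,
                 ms_between = msb, ms_within = msw,
                 F = F, p = pf(F, dfb, dfw, lower.tail = FALSE),
                 summaries = summaries),
            class = "anova_oneway")
}

#' One-way ANOVA, from raw values or group summaries
#'
#' `anova_oneway()` works on raw per-household values;
#' `anova_oneway_from_summary()` takes a table of group summaries (`label`,
#' `n`, `mean`, `sd`) and uses the identities
#' `SS_between = sum n_i (m_i - m)^2`, `SS_within = sum (n_i - 1) s_i^2`,
#' so the two agree exactly whenever the raw groups realize the summaries.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param summaries data.frame with columns `n`, `mean`, `sd` and
#'   optionally `label`.
#' @return object of class `anova_oneway` with fields `ss_between`,
#'   `ss_within`, `df_between`, `df_within`, `ms_within`, `F`, `p` and the
#'   group `summaries` used.
#' @export
anova_oneway <- function(values, groups) {
  g <- check_groups(as_groups(values, groups))
  summaries <- data.frame(label = names(g),
                          n = vapply(g, length, integer(1)),
                          mean = vapply(g, mean, numeric(1)),
                          sd = vapply(g, sd, numeric(1)),
                          row.names = NULL)
  anova_oneway_from_summary(summaries)
}

#' @rdname anova_oneway
#' @export
anova_oneway_from_summary <- function(summaries) {
  summaries <- as.data.frame(summaries)
  if (!all(c("n", "mean", "sd") %in% names(summaries)))
    stop("summaries need columns n, mean, sd", call. = FALSE)
  if (nrow(summaries) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(summaries$n < 2L)) stop("every group needs n >= 2", call. = FALSE)
  if (is.null(summaries$label)) summaries$label <- paste0("g", seq_len(nrow(summaries)))
  n <- summaries$n; m <- summaries$mean; s <- summaries$sd
  N <- sum(n); k <- length(n)
  grand <- sum(n * m) / N
  new_anova_oneway(ssb = sum(n * (m - grand)^2),
                   ssw = sum((n - 1) * s^2),
                   dfb = k - 1L, dfw = N - k,
                   summaries = summaries)
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat("One-way ANOVA\n")
  cat(sprintf("  between: SS = %.4g, df = %d\n", x$ss_between, x$df_between))
  cat(sprintf("  within:  SS = %.4g, df = %d\n", x$ss_within, x$df_within))
  cat(sprintf("  F = %.4f, p = %.4g\n", x$F, x$p))
  invisible(x)
}

#' Additive two-way ANOVA with Type II sums of squares
#'
#' Fits the no-interaction linear model `y ~ A + B` by least squares and
#' reports, for each factor, the Type II sum of squares (the RSS drop from
#' adding that factor to the model already containing the other). Designs
#' may be unbalanced and cells may be empty; a rank-deficient additive
#' design raises an error. Residual df is `N - (a-1) - (b-1) - 1`.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (>= 2 levels after dropping unused).
#' @return object of class `anova_twoway`: data.frame with rows for each
#'   factor (`term`, `ss`, `df`, `F`, `p`) plus attributes `ss_residual`,
#'   `df_residual`.
#' @export
anova_twoway_additive <- function(values, factor_a, factor_b) {
  a <- droplevels(factor(factor_a))
  b <- droplevels(factor(factor_b))
  keep <- !is.na(values) & !is.na(a) & !is.na(b)
  y <- values[keep]; a <- droplevels(a[keep]); b <- droplevels(b[keep])
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both factors need at least 2 levels", call. = FALSE)
  N <- length(y)
  rss <- function(X) {
    fit <- lm.fit(X, y)
    list(rss = sum(fit$residuals^2), rank = fit$rank, p = ncol(X))
  }
  Xab <- stats::model.matrix(~ a + b)
  full <- rss(Xab)
  if (full$rank < full$p)
    stop("rank-deficient additive design (aliased factor levels)", call. = FALSE)
  ra <- rss(stats::model.matrix(~ a))$rss
  rb <- rss(stats::model.matrix(~ b))$rss
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_res <- N - df_a - df_b - 1L
  ms_res <- full$rss / df_res
  ss <- c(rb - full$rss, ra - full$rss)
  df <- c(df_a, df_b)
  F <- (ss / df) / ms_res
  out <- data.frame(term = c("A", "B"), ss = ss, df = df, F = F,
                    p = pf(F, df, df_res, lower.tail = FALSE))
  structure(out, ss_residual = full$rss, df_residual = df_res,
            class = c("anova_twoway", "data.frame"))
}

#' @export
print.anova_twoway <- function(x, ...) {
  cat("Additive two-way ANOVA (Type II SS)\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("  residual: SS = %.4g, df = %d\n",
              attr(x, "ss_residual"), attr(x, "df_residual")))
  invisible(x)
}

#' Tukey-Kramer all-pairs post hoc comparisons
#'
#' For each pair of groups the standard error is
#' `sqrt((ms_within / 2) (1/n1 + 1/n2))` (which reduces to the classic
#' Tukey `sqrt(ms_within / n)` for equal n), the studentized-range
#' statistic is `q = |m1 - m2| / se`, the adjusted p-value comes from the
#' studentized-range distribution with `(k, df_within)`, and the confidence
#' interval is `diff +/- q_crit * se` with `q_crit` the upper `conf`
#' quantile.
#'
#' Input is either raw data (`values` + `groups`) or a summary table
#' (`label`, `n`, `mean`, `sd`); `ms_within`/`df_within` default to the
#' pooled within-group variance of the same input but can be supplied to
#' reuse an ANOVA's error term.
#'
#' @param values,groups raw data (alternative to `summaries`).
#' @param summaries group summary data.frame.
#' @param ms_within,df_within error-term override.
#' @param conf confidence level of the intervals.
#' @return data.frame of class `tukey_kramer` with one row per pair:
#'   `group1`, `group2`, `diff` (mean1 - mean2), `se`, `q`, `ci_low`,
#'   `ci_high`, `p_adj`.
#' @export
tukey_kramer <- function(values = NULL, groups = NULL, summaries = NULL,
                         ms_within = NULL, df_within = NULL, conf = 0.95) {
  if (is.null(summaries)) {
    if (is.null(values) || is.null(groups))
      stop("supply either summaries or values + groups", call. = FALSE)
    g <- check_groups(as_groups(values, groups))
    summaries <- data.frame(label = names(g),
                            n = vapply(g, length, integer(1)),
                            mean = vapply(g, mean, numeric(1)),
                            sd = vapply(g, sd, numeric(1)))
  }
  summaries <- as.data.frame(summaries)
  if (nrow(summaries) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(summaries$label)) summaries$label <- paste0("g", seq_len(nrow(summaries)))
  if (is.null(ms_within) || is.null(df_within)) {
    a <- anova_oneway_from_summary(summaries)
    ms_within <- a$ms_within
    df_within <- a$df_within
  }
  if (ms_within <= 0) stop("ms_within must be > 0", call. = FALSE)
  k <- nrow(summaries)
  pairs <- combn(k, 2L)
  i <- pairs[1L, ]; j <- pairs[2L, ]
  diff <- summaries$mean[i] - summaries$mean[j]
  se <- sqrt(ms_within / 2 * (1 / summaries$n[i] + 1 / summaries$n[j]))
  q <- abs(diff) / se
  qc <- qtukey(conf, k, df_within)
  out <- data.frame(group1 = summaries$label[i], group2 = summaries$label[j],
                    diff = diff, se = se, q = q,
                    ci_low = diff - qc * se, ci_high = diff + qc * se,
                    p_adj = ptukey(q, k, df_within, lower.tail = FALSE))
  structure(out, ms_within = ms_within, df_within = df_within, conf = conf,
            class = c("tukey_kramer", "data.frame"))
}

#' @export
print.tukey_kramer <- function(x, ...) {
  cat(sprintf("Tukey-Kramer comparisons (MS_within = %.4g, df = %d)\n",
              attr(x, "ms_within"), attr(x, "df_within")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sample-size-weighted grand mean of group summaries
#'
#' @param summaries data.frame with columns `n` and `mean` (e.g. one
#'   indicator block of [dyd_summary_tables()]).
#' @return `sum(n * mean) / sum(n)`.
#' @export
grand_weighted_mean <- function(summaries) {
  summaries <- as.data.frame(summaries)
  if (nrow(summaries) < 1L) stop("need at least one group", call. = FALSE)
  sum(summaries$n * summaries$mean) / sum(summaries$n)
}

#' Read a group-summary CSV
#'
#' Expected columns: `label`, `n`, `mean`, `sd` (indicator units, minutes),
#' optionally `indicator` to hold several blocks in one file.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_summary_csv <- function(path) {
  dt <- data.table::fread(path)
  need <- c("label", "n", "mean", "sd")
  if (!all(need %in% names(dt)))
    stop(sprintf("summary CSV %s lacks columns: %s", path,
                 paste(setdiff(need, names(dt)), collapse = ", ")), call. = FALSE)
  as.data.frame(dt)
}
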