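# Diagonal-covariance Gaussian mixture segmentation of binary activity
# vectors, with BIC model selection over the number of components.
#
# The vectors are 0/1, so a full-covariance mixture in 32 or 48 dimensions
# is degenerate; a per-dimension (diagonal) model with a variance floor is
# fitted by EM, initialized from k-means.

log_dens_diag <- function(X, mu, v) {
  # rowwise log N(x | mu, diag(v))
  cst <- -0.5 * sum(log(2 * pi * v))
  Z <- sweep(X, 2L, mu)
  cst - 0.5 * as.numeric(Z^2 %*% (1 / v))
}

fit_gmm_diag_k <- function(X, k, var_floor = 0.05, max_iter = 300L, tol = 1e-8) {
  n <- nrow(X); d <- ncol(X)
  X2 <- X * X
  if (k == 1L) {
    mu <- matrix(colMeans(X), nrow = 1L)
    v <- matrix(pmax(colMeans(X2) - mu[1L, ]^2, var_floor), nrow = 1L)
    ll <- sum(log_dens_diag(X, mu[1L, ], v[1L, ]))
    return(list(k = 1L, prop = 1, mean = mu, var = v,
                loglik = ll, assign = rep(1L, n), resp = matrix(1, n, 1L)))
  }
  # initialization only: EM refines from here, so kmeans convergence
  # warnings are immaterial
  km <- suppressWarnings(kmeans(X, centers = k, nstart = 5L, iter.max = 100L))
  grp <- km$cluster
  nk <- pmax(as.numeric(tabulate(grp, k)), 1e-12)
  prop <- nk / n
  G <- matrix(0, n, k); G[cbind(seq_len(n), grp)] <- 1
  mu <- crossprod(G, X) / nk
  v <- pmax(crossprod(G, X2) / nk - mu^2, var_floor)
  ll_old <- -Inf
  resp <- NULL
  for (iter in seq_len(max_iter)) {
    # E step: log p(x|j) expanded as -(x^2/2v) + (mu/v)x - (mu^2/2v + log(2*pi*v)/2)
    cst <- log(prop) - 0.5 * rowSums(mu^2 / v + log(2 * pi * v))
    L <- X %*% t(mu / v) - 0.5 * (X2 %*% t(1 / v))
    L <- sweep(L, 2L, cst, "+")
    m <- L[, 1L]
    for (j in seq_len(k)[-1L]) m <- pmax(m, L[, j])
    W <- exp(L - m)
    rs <- rowSums(W)
    ll <- sum(m + log(rs))
    resp <- W / rs
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
    # M step
    nk <- pmax(colSums(resp), 1e-12)
    prop <- nk / n
    mu <- crossprod(resp, X) / nk
    v <- pmax(crossprod(resp, X2) / nk - mu^2, var_floor)
  }
  list(k = k, prop = prop, mean = mu, var = v, loglik = ll,
       assign = max.col(resp, ties.method = "first"), resp = resp)
}

gmm_bic <- function(fit, n, d) {
  npar <- (fit$k - 1) + 2 * fit$k * d
  -2 * fit$loglik + npar * log(n)
}

fit_activity_gmm <- function(X, k_max = 6L, seed = 1L, var_floor = 0.05) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  n_distinct <- nrow(unique(X))
  ks <- seq_len(max(1L, min(k_max, n_distinct)))
  with_preserved_seed(seed, {
    fits <- lapply(ks, function(k) {
      tryCatch(fit_gmm_diag_k(X, k, var_floor = var_floor),
               error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, logical(1))
    fits <- fits[ok]; ks <- ks[ok]
    bic <- vapply(fits, gmm_bic, numeric(1), n = n, d = d)
    best <- which.min(bic)  # ties resolve to the smaller k
    fit <- fits[[best]]
    structure(list(k = fit$k, prop = fit$prop, mean = fit$mean,
                   var = fit$var, loglik = fit$loglik, assign = fit$assign,
                   bic = stats::setNames(bic, paste0("k", ks)),
                   n = n, d = d, seed = seed),
              class = "activity_gmm")
  })
}

#' Cluster sleep-cycle or daily activity vectors
#'
#' Segments a household's binary activity records into behavioural clusters
#' using a diagonal-covariance Gaussian mixture fitted by EM (k-means
#' initialization). The number of components is
#' chosen by minimizing BIC over `1..k_max`, with ties resolved to the
#' smaller k; records are hard-assigned to their maximum-posterior
#' component. Fits are deterministic for a fixed `seed`.
#'
#' `fit_cycle_clusters()` takes 32-slot sleep cycles; `fit_daily_clusters()`
#' takes 48-slot daily vectors. When fewer than `min_records` records are
#' supplied the household is excluded from the stratum: the functions return
#' an exclusion sentinel (reason `"insufficient_records"`) rather than
#' raising; test with [is_excluded()].
#'
#' @param x a `sleep_cycles` / `daily_activity` object, or a binary matrix
#'   with 32 (cycles) or 48 (daily) columns.
#' @param k_max largest number of mixture components tried.
#' @param seed RNG seed for the k-means initializations.
#' @param min_records minimum records required to attempt a fit.
#' @param var_floor per-dimension variance floor. The default 0.05 (the
#'   Bernoulli variance at p of about 0.05) stops near-constant binary
#'   dimensions from dominating the likelihood, which would otherwise make
#'   BIC saturate at `k_max` and cluster on sensor noise.
#' @return an object of class `activity_gmm` (fields `k`, `prop`, `mean`,
#'   `var`, `assign`, `bic`, `n`, `d`), or `NULL` when excluded.
#' @export
fit_cycle_clusters <- function(x, k_max = 6L, seed = 1L, min_records = 10L,
                               var_floor = 0.05) {
  X <- if (inherits(x, "sleep_cycles")) x$cycles else as.matrix(x)
  if (ncol(X) != 32L) stop("sleep cycles must have 32 slots", call. = FALSE)
  if (nrow(X) < min_records)
    return(excluded("insufficient_records"))
  fit_activity_gmm(X, k_max = k_max, seed = seed, var_floor = var_floor)
}

#' @rdname fit_cycle_clusters
#' @export
fit_daily_clusters <- function(x, k_max = 6L, seed = 1L, min_records = 10L,
                               var_floor = 0.05) {
  X <- if (inherits(x, "daily_activity")) x$slots else as.matrix(x)
  if (ncol(X) != 48L) stop("daily vectors must have 48 slots", call. = FALSE)
  if (nrow(X) < min_records)
    return(excluded("insufficient_records"))
  fit_activity_gmm(X, k_max = k_max, seed = seed, var_floor = var_floor)
}

#' @export
print.activity_gmm <- function(x, ...) {
  cat(sprintf("<activity_gmm> k = %d over %d records x %d slots; weights: %s\n",
              x$k, x$n, x$d, paste(sprintf("%.3f", x$prop), collapse = ", ")))
  invisible(x)
}
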