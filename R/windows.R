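# One-dimensional Gaussian mixture fit by EM.
#
# "quantile" initialization splits the sorted data into k contiguous blocks
# and seeds each component from its block's mean/variance/proportion -- a
# deterministic emulation of variance-partitioning starts that keeps the
# forward search reproducible. "kmeans" initialization is available as an
# alternative (uses the session RNG).
gmm1d_fit <- function(x, k, init = c("quantile", "kmeans"),
                      max_iter = 500L, tol = 1e-8) {
  init <- match.arg(init)
  n <- length(x)
  if (k > n) stop("more components than observations")
  var_floor <- max(1e-6, 1e-6 * stats::var(x))
  if (k == 1L) {
    mu <- mean(x)
    s2 <- max(stats::var(x) * (n - 1) / n, var_floor)
    ll <- sum(dnorm(x, mu, sqrt(s2), log = TRUE))
    return(list(k = 1L, mu = mu, sigma2 = s2, prop = 1,
                loglik = ll, bic = -2 * ll + 2 * log(n), converged = TRUE))
  }
  if (init == "quantile") {
    xs <- sort(x)
    blocks <- split(xs, cut(seq_len(n), k, labels = FALSE))
  } else {
    km <- stats::kmeans(x, centers = k, nstart = 5)
    blocks <- split(x, km$cluster)
  }
  mu <- vapply(blocks, mean, 0)
  s2 <- pmax(vapply(blocks, function(b)
    if (length(b) > 1L) stats::var(b) else 0, 0), var_floor)
  prop <- vapply(blocks, length, 0L) / n
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(g)
      prop[g] * dnorm(x, mu[g], sqrt(s2[g])), numeric(n))
    tot <- rowSums(dens)
    if (any(tot <= 0) || any(!is.finite(tot)))
      return(list(k = k, converged = FALSE))
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(list(k = k, converged = FALSE))
    prop <- nk / n
    mu <- colSums(resp * x) / nk
    s2 <- pmax(colSums(resp * (outer(x, mu, "-"))^2) / nk, var_floor)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + tol)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  npar <- 3L * k - 1L
  list(k = k, mu = mu, sigma2 = s2, prop = prop, loglik = ll_old,
       bic = -2 * ll_old + npar * log(n), converged = converged)
}

#' Screen trial windows for firing-rate homogeneity
#'
#' Detects and removes task windows with aberrant spike counts. Windows with
#' fewer than 2 spikes are dropped outright. The remaining counts are
#' clustered with 1-D Gaussian mixtures in a forward search over the number
#' of components: `k` grows from 1 until the BIC rises or a fit fails, and
#' the previous model is kept. Windows are hard-assigned to the most
#' probable component; only the component holding the most windows is
#' retained, and counts more than 3 component SDs from its mean are dropped
#' as outliers.
#'
#' @param spike_counts integer vector of spikes per window.
#' @param init mixture initialization: deterministic `"quantile"` blocks
#'   (default) or `"kmeans"`.
#' @param max_k optional cap on the forward search (default: number of
#'   screened windows).
#' @return a `window_screen` list: `kept` (indices into `spike_counts`),
#'   `k_selected`, `cluster_params` (data.frame `mu`, `sigma`, `prop`),
#'   `assigned` (component per screened window), `dropped_low`,
#'   `dropped_outlier`, `bic_trace`.
#' @export
select_windows <- function(spike_counts, init = "quantile", max_k = NULL) {
  stopifnot(is.numeric(spike_counts))
  idx_all <- seq_along(spike_counts)
  low <- idx_all[spike_counts < 2]
  keep0 <- idx_all[spike_counts >= 2]
  if (length(keep0) == 0L)
    stop("all windows report < 2 spikes")
  x <- as.numeric(spike_counts[keep0])
  if (is.null(max_k)) max_k <- length(x)
  fits <- list()
  bic <- numeric(0)
  for (k in seq_len(max_k)) {
    f <- gmm1d_fit(x, k, init = init)
    if (!isTRUE(f$converged)) break
    fits[[k]] <- f
    bic[k] <- f$bic
    if (k > 1L && bic[k] > bic[k - 1L]) break
  }
  k_sel <- if (length(bic) > 1L && bic[length(bic)] > bic[length(bic) - 1L])
    length(bic) - 1L else length(bic)
  fit <- fits[[k_sel]]
  resp <- vapply(seq_len(fit$k), function(g)
    fit$prop[g] * dnorm(x, fit$mu[g], sqrt(fit$sigma2[g])), numeric(length(x)))
  assigned <- if (fit$k == 1L) rep(1L, length(x))
              else max.col(resp, ties.method = "first")
  big <- which.max(tabulate(assigned, nbins = fit$k))
  in_big <- assigned == big
  sig_g <- sqrt(fit$sigma2[big])
  outlier <- in_big & abs(x - fit$mu[big]) > 3 * sig_g
  kept <- keep0[in_big & !outlier]
  structure(
    list(kept = kept, k_selected = fit$k,
         cluster_params = data.frame(mu = fit$mu, sigma = sqrt(fit$sigma2),
                                     prop = fit$prop),
         assigned = assigned, dropped_low = low,
         dropped_outlier = keep0[outlier], bic_trace = bic),
    class = "window_screen")
}

#' @export
print.window_screen <- function(x, ...) {
  cat(sprintf(
    "window_screen: kept %d window(s), k = %d, dropped %d low / %d outlier\n",
    length(x$kept), x$k_selected, length(x$dropped_low),
    length(x$dropped_outlier)))
  invisible(x)
}

#' Unit-level inclusion decision after window screening
#'
#' Discards units for which too few windows survive screening or the mean
#' firing rate over surviving windows is too low.
#'
#' @param n_windows number of surviving windows.
#' @param mean_fr mean firing rate over surviving windows, Hz.
#' @param min_windows minimum surviving windows (default 30).
#' @param min_fr minimum mean rate in Hz (default 1).
#' @return list with `keep` (logical) and `reasons` (character vector, empty
#'   when kept).
#' @export
screen_unit <- function(n_windows, mean_fr, min_windows = 30L, min_fr = 1) {
  reasons <- character(0)
  if (n_windows < min_windows)
    reasons <- c(reasons, sprintf("fewer than %d surviving windows (%d)",
                                  min_windows, n_windows))
  if (mean_fr < min_fr)
    reasons <- c(reasons, sprintf("mean rate below %g Hz (%.3g Hz)",
                                  min_fr, mean_fr))
  list(keep = length(reasons) == 0L, reasons = reasons)
}
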