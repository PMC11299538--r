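#' Last-spike latency of every bin
#'
#' For each bin `t` returns `t - s(t)` where `s(t)` is the time of the most
#' recent spike strictly before `t`, or 0 when no spike precedes `t`.
#'
#' @param delta 0/1 vector (or `spike_train`).
#' @return integer vector of latencies (0 = no previous spike).
#' @keywords internal
last_spike_lag <- function(delta) {
  if (inherits(delta, "spike_train")) delta <- delta$delta
  T <- length(delta)
  cm <- cummax(ifelse(delta != 0L, seq_len(T), 0L))
  prev <- c(0L, cm[-T])
  ifelse(prev == 0L, 0L, seq_len(T) - prev)
}

#' Design description for the bounded last-spike model
#'
#' The model regresses the log spike intensity at bin `t` on an intercept
#' plus indicator regressors for the latency of the most recent spike, but
#' only when that spike fell within the preceding `n_r_hat` ms: indicator
#' `j` (for `j = 1..n_r_hat`) is active at `t` iff the last spike strictly
#' before `t` occurred exactly `j` ms ago. At most one indicator is active
#' per row; all are 0 when the last spike is older than `n_r_hat` ms or
#' absent. Rows cover `t` in `[n_r_hat + 1, T]`, where the model (and its
#' residuals) are defined.
#'
#' @param train a `spike_train`.
#' @param n_r_hat history bound in ms (>= 1).
#' @return a `ppm_design`: list with `rows` (fitted bins), `lag` (latency per
#'   fitted bin), `group` (active indicator per row, 0 = none), `y`
#'   (response), `n_r_hat`.
#' @export
build_design <- function(train, n_r_hat) {
  stopifnot(inherits(train, "spike_train"))
  n_r_hat <- as.integer(n_r_hat)
  if (n_r_hat < 1L) stop("n_r_hat must be >= 1")
  delta <- train$delta
  T <- length(delta)
  if (n_r_hat + 1L > T) stop("train shorter than n_r_hat + 1")
  rows <- (n_r_hat + 1L):T
  lag <- last_spike_lag(delta)[rows]
  group <- ifelse(lag >= 1L & lag <= n_r_hat, lag, 0L)
  structure(list(rows = rows, lag = lag, group = group,
                 y = delta[rows], n_r_hat = n_r_hat),
            class = "ppm_design")
}

#' Dense indicator matrix of a design (for cross-checks)
#'
#' Materializes the `length(rows) x n_r_hat` indicator matrix implied by a
#' [build_design()] description. Intended for small inputs (tests, oracles).
#'
#' @param design a `ppm_design`.
#' @return numeric matrix with one column per lag indicator.
#' @export
design_indicator_matrix <- function(design) {
  stopifnot(inherits(design, "ppm_design"))
  X <- matrix(0, nrow = length(design$rows), ncol = design$n_r_hat)
  act <- design$group > 0L
  X[cbind(which(act), design$group[act])] <- 1
  colnames(X) <- paste0("lag", seq_len(design$n_r_hat))
  X
}

#' Fit the bounded last-spike Poisson model
#'
#' Maximum-likelihood fit of the Poisson log-linear model
#' `log lambda(t) = beta0 + sum_j beta_j d_j(t)` over the design of
#' [build_design()]. Because the lag indicators are mutually exclusive, the
#' rows partition into `n_r_hat + 1` groups (one per active indicator, plus
#' the no-recent-spike group) and the unique likelihood maximizer fits each
#' group's intensity to its observed spike fraction; the concave
#' log-likelihood guarantees this grouped solution is the same optimum that
#' iteratively re-weighted least squares converges to (checked against
#' `stats::glm.fit` in the test suite). The canonical-link score identities
#' (residuals summing to zero overall and against every regressor) therefore
#' hold to machine precision.
#'
#' A lag never followed by any spike (e.g. inside an absolute refractory
#' period) drives its coefficient to minus infinity; such coefficients are
#' floored at -30 (intensity indistinguishable from zero, keeping the score identities intact to ~1e-11) with a warning rather than failing.
#' Lags that never occur in the data are dropped from the fit and reported
#' in `dropped_lags`.
#'
#' @param train a `spike_train`.
#' @param n_r_hat history bound in ms (>= 1), typically from
#'   [estimate_rp_duration()].
#' @return a `ppm_fit`: `beta0`, `beta` (named `lag1..`, `NA` for dropped
#'   lags), `n_r_hat`, `fitted_rows` (range), `converged`, `loglik`,
#'   `separated` (lags hitting the floor), `dropped_lags`, and the internal
#'   `group` vector reused by [residual_series()].
#' @export
fit_bounded_last_spike <- function(train, n_r_hat) {
  d <- build_design(train, n_r_hat)
  if (sum(d$y) < 1L) stop("no spikes in the fitted range")
  nr <- d$n_r_hat
  grp <- factor(d$group, levels = 0:nr)
  n_g <- as.numeric(table(grp))
  s_g <- as.numeric(tapply(d$y, grp, sum, default = 0))
  mu_g <- ifelse(n_g > 0, s_g / n_g, NA_real_)

  floor_log <- -30
  separated <- integer(0)
  if (n_g[1L] == 0L) stop("no baseline rows outside the history bound")
  beta0 <- if (mu_g[1L] > 0) log(mu_g[1L]) else floor_log
  beta <- rep(NA_real_, nr)
  for (j in seq_len(nr)) {
    if (n_g[j + 1L] == 0) next                    # unpopulated lag: dropped
    if (mu_g[j + 1L] > 0) {
      beta[j] <- log(mu_g[j + 1L]) - beta0
    } else {
      beta[j] <- floor_log
      separated <- c(separated, j)
    }
  }
  if (length(separated))
    warning("lag(s) ", paste(separated, collapse = ", "),
            " never followed by a spike; coefficient(s) floored at ",
            floor_log)
  names(beta) <- paste0("lag", seq_len(nr))
  dropped <- which(n_g[-1L] == 0)

  eta <- beta0 + ifelse(d$group > 0L, beta[pmax(d$group, 1L)], 0)
  mu <- exp(eta)
  if (any(mu > 1 + 1e-8, na.rm = TRUE))
    warning("fitted per-ms intensity exceeds 1 for some rows")
  loglik <- sum(d$y * eta - mu)
  structure(
    list(beta0 = beta0, beta = beta, n_r_hat = nr,
         fitted_rows = range(d$rows), converged = TRUE, loglik = loglik,
         separated = separated, dropped_lags = dropped,
         group = d$group, rows = d$rows),
    class = "ppm_fit")
}

#' @export
print.ppm_fit <- function(x, ...) {
  cat(sprintf(
    "ppm_fit: n_r_hat=%d, beta0=%.4f (rate %.2f Hz), loglik=%.2f\n",
    x$n_r_hat, x$beta0, 1000 * exp(x$beta0), x$loglik))
  cat("  exp(beta_j):",
      paste(sprintf("%.3f", exp(x$beta)), collapse = ", "), "\n")
  invisible(x)
}

#' Raw residual series of a fitted point-process model
#'
#' `r(t) = I(t) - exp(beta0 + sum_j beta_j d_j(t))`, the observed spike
#' indicator minus the fitted intensity, defined for
#' `t >= n_r_hat + 1`; the leading `n_r_hat` positions are zero.
#'
#' @param train the `spike_train` the model was fit to.
#' @param fit a `ppm_fit` from [fit_bounded_last_spike()].
#' @return a `residual_series`: list with `r` (length-`T` numeric) and
#'   `pad_len = n_r_hat`.
#' @export
residual_series <- function(train, fit) {
  stopifnot(inherits(train, "spike_train"), inherits(fit, "ppm_fit"))
  T <- length(train$delta)
  if (fit$fitted_rows[2L] != T)
    stop("fit does not match this train's length")
  beta_row <- ifelse(fit$group > 0L, fit$beta[pmax(fit$group, 1L)], 0)
  mu <- exp(fit$beta0 + beta_row)
  r <- numeric(T)
  r[fit$rows] <- train$delta[fit$rows] - mu
  structure(list(r = r, pad_len = fit$n_r_hat), class = "residual_series")
}

#' Residuals-corrected PSD of an unbroken spike train
#'
#' The full residuals pipeline: estimate the recovery-period duration (unless
#' supplied), fit the bounded last-spike Poisson model, form the raw residual
#' series, and take its Welch PSD. Following the segment conventions, the
#' first 1024-ms segment consists of the initial `1024 - n_r_hat` ms of
#' residuals, demeaned and prepended with `n_r_hat` ms of zero padding;
#' subsequent segments are the raw residual stream in 1024-ms blocks,
#' demeaned by the Welch stage.
#'
#' @param train a `spike_train` whose length is a multiple of 1024.
#' @param n_r_hat optional history bound in ms; estimated internally from the
#'   ISI distribution when `NULL`.
#' @param max_lag,min_isis passed to [estimate_rp_duration()].
#' @return a list of class `residuals_psd` with elements `psd` (the
#'   corrected spectrum), `rp` (`rp_estimate` or `NULL` when `n_r_hat` was
#'   supplied), `fit` (`ppm_fit`), `residuals` (`residual_series`), and
#'   `method = "residuals"`.
#' @export
residuals_corrected_psd <- function(train, n_r_hat = NULL, max_lag = 100L,
                                    min_isis = 50L) {
  stopifnot(inherits(train, "spike_train"))
  T <- length(train$delta)
  if (T %% 1024L != 0L) stop("train length must be a multiple of 1024")
  rp <- NULL
  if (is.null(n_r_hat)) {
    rp <- estimate_rp_duration(train, max_lag = max_lag, min_isis = min_isis)
    n_r_hat <- rp$n_r_hat
  }
  fit <- fit_bounded_last_spike(train, n_r_hat)
  res <- residual_series(train, fit)
  x <- res$r
  nr <- fit$n_r_hat
  seg1 <- x[(nr + 1L):1024L]
  x[1:1024] <- c(numeric(nr), seg1 - mean(seg1))
  psd <- welch_psd(x, demean_per_segment = TRUE)
  structure(list(psd = psd, rp = rp, fit = fit, residuals = res,
                 method = "residuals"),
            class = "residuals_psd")
}

#' Residuals-corrected PSD for trial-windowed data
#'
#' Windowed analogue of [residuals_corrected_psd()]. The recovery period is
#' estimated from the pooled within-row ISIs; the Poisson model is fit once,
#' pooled over all rows, with spike history reset at every row boundary (no
#' memory crosses trials) and the first `n_r_hat` ms of each row unfitted.
#' Each row's residuals (length `W - n_r_hat`) are demeaned, prepended with
#' `n_r_hat` ms and appended with `1024 - W` ms of zeros, and the resulting
#' 1024-ms segments averaged by the Welch stage.
#'
#' @param trials a `trial_matrix` with rows of length <= 1024.
#' @param n_r_hat optional history bound; estimated from pooled ISIs when
#'   `NULL`.
#' @param max_lag,min_isis passed to the recovery-period estimator.
#' @return a `residuals_psd` list (see [residuals_corrected_psd()]).
#' @export
residuals_corrected_psd_windowed <- function(trials, n_r_hat = NULL,
                                             max_lag = 100L, min_isis = 50L) {
  trials <- as.matrix(trials)
  nD <- nrow(trials)
  W <- ncol(trials)
  if (W > 1024L) stop("rows longer than the 1024 ms segment size")
  if (sum(trials) < 1L) stop("trial matrix contains no spikes")
  isis <- integer(0)
  for (i in seq_len(nD)) {
    st <- which(trials[i, ] != 0)
    if (length(st) >= 2L) isis <- c(isis, diff(st))
  }
  rp <- NULL
  if (is.null(n_r_hat)) {
    if (length(isis) < 2L) stop("too few within-row ISIs to estimate the RP")
    rp <- estimate_rp_from_isis(isis, max_lag = max_lag, min_isis = min_isis)
    n_r_hat <- rp$n_r_hat
  }
  nr <- as.integer(n_r_hat)
  if (nr + 1L > W) stop("n_r_hat too large for the window length")

  # pooled grouped MLE with per-row history
  rows_per <- (nr + 1L):W
  grp_all <- integer(0)
  y_all <- integer(0)
  lag_mat <- matrix(0L, nD, W)
  for (i in seq_len(nD)) {
    lag <- last_spike_lag(trials[i, ])
    lag_mat[i, ] <- lag
    g <- ifelse(lag[rows_per] >= 1L & lag[rows_per] <= nr,
                lag[rows_per], 0L)
    grp_all <- c(grp_all, g)
    y_all <- c(y_all, trials[i, rows_per])
  }
  if (sum(y_all) < 1L) stop("no spikes in the fitted range")
  grp <- factor(grp_all, levels = 0:nr)
  n_g <- as.numeric(table(grp))
  s_g <- as.numeric(tapply(y_all, grp, sum, default = 0))
  mu_g <- ifelse(n_g > 0, s_g / n_g, NA_real_)
  floor_log <- -30
  if (n_g[1L] == 0L) stop("no baseline rows outside the history bound")
  beta0 <- if (mu_g[1L] > 0) log(mu_g[1L]) else floor_log
  beta <- rep(NA_real_, nr)
  for (j in seq_len(nr)) {
    if (n_g[j + 1L] == 0) next
    beta[j] <- if (mu_g[j + 1L] > 0) log(mu_g[j + 1L]) - beta0 else floor_log
  }
  names(beta) <- paste0("lag", seq_len(nr))
  eta_all <- beta0 + ifelse(grp_all > 0L, beta[pmax(grp_all, 1L)], 0)
  fit <- structure(
    list(beta0 = beta0, beta = beta, n_r_hat = nr,
         fitted_rows = c(nr + 1L, W), converged = TRUE,
         loglik = sum(y_all * eta_all - exp(eta_all)),
         separated = which(!is.na(beta) & beta <= floor_log),
         dropped_lags = which(n_g[-1L] == 0),
         group = NULL, rows = NULL),
    class = "ppm_fit")

  # per-row residual segments
  segs <- matrix(0, nrow = 1024L, ncol = nD)
  for (i in seq_len(nD)) {
    lag <- lag_mat[i, rows_per]
    g <- ifelse(lag >= 1L & lag <= nr, lag, 0L)
    mu <- exp(beta0 + ifelse(g > 0L, beta[pmax(g, 1L)], 0))
    r <- trials[i, rows_per] - mu
    segs[(nr + 1L):W, i] <- r - mean(r)
  }
  psd <- new_psd(cpp_psd_from_segments(segs), nD)
  structure(list(psd = psd, rp = rp, fit = fit, residuals = NULL,
                 method = "residuals"),
            class = "residuals_psd")
}

#' @export
print.residuals_psd <- function(x, ...) {
  cat(sprintf("residuals_psd: n_r_hat=%d, %d segment(s)\n",
              x$fit$n_r_hat, x$psd$n_segments))
  invisible(x)
}
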