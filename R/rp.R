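#' Inter-spike intervals of a train
#'
#' @param train a `spike_train` (or 0/1 vector).
#' @return integer vector of successive spike-time differences in ms.
#' @export
isi_list <- function(train) {
  st <- spike_times(train)
  if (length(st) < 2L) stop("need at least 2 spikes to form ISIs")
  diff(st)
}

# Poisson log-link GLM of pdf values on lag, fitted by IRLS with
# step-halving on the deviance from the null start (b0 = log(mean(y)),
# b1 = 0), so the achieved deviance never exceeds the null deviance and the
# deviance difference D0 - D1 = -2*(logL0 - logL1) is nonnegative.
poisson_deviance <- function(y, mu) {
  2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
}

fit_log_linear <- function(x, y, max_iter = 50L, tol = 1e-12) {
  ybar <- mean(y)
  if (ybar <= 0) stop("mean of the response must be positive")
  b <- c(log(ybar), 0)
  dev <- poisson_deviance(y, rep(ybar, length(y)))
  X <- cbind(1, x)
  for (it in seq_len(max_iter)) {
    eta <- b[1] + b[2] * x
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    step_b <- tryCatch(
      as.numeric(solve(crossprod(X, mu * X), crossprod(X, mu * z))) - b,
      error = function(e) NULL)
    if (is.null(step_b)) break
    lam <- 1
    improved <- FALSE
    for (h in 1:30) {
      bn <- b + lam * step_b
      dev_n <- poisson_deviance(y, exp(bn[1] + bn[2] * x))
      if (is.finite(dev_n) && dev_n <= dev) {
        improved <- dev - dev_n > tol * max(dev, 1e-300)
        b <- bn
        dev <- dev_n
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  list(b0 = b[1], b1 = b[2], deviance = dev,
       null_deviance = poisson_deviance(y, rep(ybar, length(y))))
}

#' Right-shifted exponential fit to a cropped ISI density
#'
#' Fits the scaled exponential `pdf(x) = exp(B0 + B1 x)` over the supplied
#' support (a Poisson generalized linear model with log link, fitted by
#' iteratively re-weighted least squares), together with the nested
#' constant-only model, and returns the deviance difference
#' `delta_D = D0 - D1 = -2 (logL0 - logL1) >= 0` measuring the explanatory
#' value of the exponential lag term.
#'
#' @param lags integer lag support (ms).
#' @param pdf nonnegative density values over `lags` (unit area over the
#'   crop).
#' @return list with `B0`, `B1`, `D0` (constant-only deviance), `D1` (full
#'   model deviance) and `delta_D`.
#' @export
shifted_exponential_fit <- function(lags, pdf) {
  stopifnot(length(lags) == length(pdf))
  if (length(lags) < 3L) stop("need at least 3 support points")
  if (sum(pdf) <= 0) stop("density has no mass over the support")
  if (sum(pdf > 0) < 2L)
    stop("degenerate support: all mass in a single bin")
  fit <- fit_log_linear(as.numeric(lags), as.numeric(pdf))
  list(B0 = fit$b0, B1 = fit$b1, D0 = fit$null_deviance, D1 = fit$deviance,
       delta_D = fit$null_deviance - fit$deviance)
}

estimate_rp_from_isis <- function(isis, max_lag = 100L, min_isis = 50L) {
  if (length(isis) < min_isis)
    stop("too few ISIs (", length(isis), " < ", min_isis,
         ") for a stable recovery-period estimate")
  max_isi <- max(isis)
  counts <- tabulate(isis, nbins = max_isi)
  trace <- data.frame(L = integer(0), B0 = numeric(0), B1 = numeric(0),
                      D0 = numeric(0), D1 = numeric(0), delta_D = numeric(0))
  n_r_hat <- NA_integer_
  for (L in seq_len(min(max_lag, max_isi - 2L))) {
    support <- L:max_isi
    mass <- sum(counts[support])
    if (length(support) < 3L || mass == 0) break
    pdf <- counts[support] / mass
    f <- tryCatch(shifted_exponential_fit(support, pdf),
                  error = function(e) NULL)
    if (is.null(f)) break
    trace[nrow(trace) + 1L, ] <- list(L, f$B0, f$B1, f$D0, f$D1, f$delta_D)
    n <- nrow(trace)
    if (n >= 3L) {
      dd <- trace$delta_D
      if (dd[n - 2L] < dd[n - 1L] && dd[n - 1L] > dd[n]) {
        n_r_hat <- trace$L[n - 1L] - 1L
        break
      }
    }
  }
  trace$p_chisq <- pchisq(trace$delta_D, df = 1, lower.tail = FALSE)
  if (is.na(n_r_hat)) {
    cond <- structure(
      class = c("rpspect_no_local_max", "error", "condition"),
      list(message = paste0(
             "no interior local maximum of the deviance difference found ",
             "within max_lag = ", max_lag, " ms"),
           call = sys.call(-1), trace = trace))
    stop(cond)
  }
  structure(list(n_r_hat = n_r_hat, trace = trace,
                 max_lag_searched = max(trace$L)),
            class = "rp_estimate")
}

#' Estimate the recovery-period duration from the ISI distribution
#'
#' Implements the deviance-difference scan: for each candidate start lag `L`
#' the ISI histogram is cropped to `[L, max(ISI)]`, renormalized to unit
#' area, and fit with a right-shifted exponential ([shifted_exponential_fit()]).
#' The deviance difference `delta_D(L)` between the exponential and
#' constant-only models peaks when the crop first excludes the whole
#' recovery period, because firing outside the recovery period is
#' (approximately) Poisson. The scan stops at the first interior local
#' maximum `delta_D(L-1) < delta_D(L) > delta_D(L+1)` and returns
#' `n_r_hat = L - 1` ms. Equivalently, the first local minimum of the
#' chi-squared(1) p-values of `delta_D` identifies the same lag (column
#' `p_chisq` of the trace).
#'
#' The smallest returnable estimate is 1 ms (the first testable local
#' maximum sits at `L = 2`). Estimation is deterministic given the train.
#'
#' @param train a `spike_train`.
#' @param max_lag largest start lag searched, ms (default 100).
#' @param min_isis minimum number of ISIs required (default 50).
#' @return an `rp_estimate`: `n_r_hat` (ms), `trace` (one row per fitted lag
#'   with `L`, `B0`, `B1`, `D0`, `D1`, `delta_D`, `p_chisq`) and
#'   `max_lag_searched`. Errors (with the trace attached to the condition)
#'   when no local maximum is found before `max_lag`.
#' @export
estimate_rp_duration <- function(train, max_lag = 100L, min_isis = 50L) {
  estimate_rp_from_isis(isi_list(train), max_lag = max_lag,
                        min_isis = min_isis)
}

#' @export
print.rp_estimate <- function(x, ...) {
  cat(sprintf("rp_estimate: n_r_hat = %d ms (searched L = 1..%d)\n",
              x$n_r_hat, x$max_lag_searched))
  invisible(x)
}
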