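#' Simulation parameters for a synthetic spike train
#'
#' Bundles the parameters of the discrete-time inhomogeneous Poisson process
#' used throughout the package. At 1 kHz resolution, the per-bin spike
#' probability is
#' \deqn{p_{spk}(t) = p_{ss}(t) = p_{base} + p_{osc} \sin(2\pi f_{osc} t/1000)}
#' when the latency \eqn{n} since the last spike exceeds the recovery-period
#' duration \eqn{n_r}, and
#' \deqn{p_{spk}(t) = p_{ss}(t) \, k^{n_r + 1 - n}}
#' while \eqn{n \le n_r} (an exponentially rising recovery). The oscillation
#' amplitude is set through the modulation index \eqn{m = p_{osc}/p_{base}},
#' never stored independently.
#'
#' @param p_base steady-state firing rate in Hz (per-bin probability
#'   `p_base/1000`).
#' @param f_osc oscillation frequency in Hz.
#' @param m modulation index in `[0, 1]`; `p_osc = m * p_base`.
#' @param n_r recovery-period duration in integer ms (>= 0).
#' @param k recovery steepness in `[0, 1)`; `k = 0` gives an absolute
#'   refractory period.
#' @param T duration in ms; must be a positive multiple of 1024 (the spectral
#'   segment size).
#' @param seed optional RNG seed stored with the parameters and applied by
#'   [simulate_spike_train()] when no explicit seed is given there.
#'
#' @return An object of class `sim_params`.
#' @examples
#' p <- sim_params(p_base = 41, f_osc = 9, m = 0.4, n_r = 9, k = 0.7,
#'                 T = 60 * 1024)
#' @export
sim_params <- function(p_base, f_osc = 0, m = 0, n_r = 0, k = 0,
                       T = 30 * 1024, seed = NULL) {
  stopifnot(is.numeric(p_base), length(p_base) == 1L, p_base >= 0)
  if (!is.numeric(m) || length(m) != 1L || m < 0 || m > 1)
    stop("m must lie in [0, 1]")
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k >= 1)
    stop("k must lie in [0, 1)")
  if (!is.numeric(n_r) || length(n_r) != 1L || n_r < 0 ||
      n_r != as.integer(n_r))
    stop("n_r must be a non-negative integer (ms)")
  if (!is.numeric(T) || length(T) != 1L || T <= 0 || T != as.integer(T) ||
      T %% 1024 != 0)
    stop("T must be a positive multiple of 1024 ms")
  p_osc <- m * p_base
  if ((p_base + p_osc) / 1000 >= 0.5)
    stop("p_base + p_osc must stay well below 500 Hz ",
         "(per-bin probability < 0.5)")
  structure(
    list(p_base = p_base, p_osc = p_osc, m = m, f_osc = f_osc,
         n_r = as.integer(n_r), k = k, T = as.integer(T), seed = seed),
    class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "sim_params: p_base=%g Hz, f_osc=%g Hz, m=%g, n_r=%d ms, k=%g, T=%d ms\n",
    x$p_base, x$f_osc, x$m, x$n_r, x$k, x$T))
  invisible(x)
}

new_spike_train <- function(delta) {
  structure(list(delta = as.integer(delta), fs = 1000), class = "spike_train")
}

#' Simulate a spike train
#'
#' Draws one Bernoulli sample per 1 ms bin from the conditional intensity
#' described in [sim_params()]. Before the first spike the unit is treated as
#' outside the recovery period (steady-state probability); a spike in bin `t`
#' sets the latency counter to 1 at bin `t + 1`. The output is a binary
#' "delta vector" of length `T` at 1 kHz, so each bin holds at most one spike.
#'
#' @param params a [sim_params()] object.
#' @param seed optional integer seed; falls back to `params$seed`. When both
#'   are `NULL` the current RNG state is used.
#' @param T_override internal: simulate a different duration than `params$T`
#'   (used for trial windows, where segments are padded later).
#' @return A `spike_train` object with fields `delta` (integer 0/1 vector) and
#'   `fs` (1000 Hz).
#' @examples
#' tr <- simulate_spike_train(sim_params(p_base = 20, T = 2048), seed = 1)
#' sum(tr$delta)
#' @export
simulate_spike_train <- function(params, seed = NULL, T_override = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  T <- if (is.null(T_override)) params$T else as.integer(T_override)
  delta <- cpp_simulate_train(T, params$p_base / 1000, params$p_osc / 1000,
                              params$f_osc, params$n_r, params$k)
  new_spike_train(delta)
}

#' Spike times of a train
#'
#' @param train a `spike_train` object (or bare 0/1 vector).
#' @return integer vector of 1-based spike times in ms.
#' @export
spike_times <- function(train) {
  delta <- if (inherits(train, "spike_train")) train$delta else train
  which(delta != 0L)
}

#' Build a spike train from spike times
#'
#' @param times integer spike times in ms (1-based bins).
#' @param T duration of the train in ms.
#' @return a `spike_train` object.
#' @export
spike_train_from_times <- function(times, T) {
  times <- as.integer(times)
  if (any(times < 1L | times > T)) stop("spike times outside [1, T]")
  if (anyDuplicated(times)) stop("duplicate spike times violate orderliness")
  delta <- integer(T)
  delta[times] <- 1L
  new_spike_train(delta)
}

#' @export
print.spike_train <- function(x, ...) {
  T <- length(x$delta)
  n <- sum(x$delta)
  cat(sprintf("spike_train: T=%d ms, %d spikes (%.2f Hz)\n",
              T, n, 1000 * n / T))
  invisible(x)
}

#' Simulate a matrix of trial windows
#'
#' Each row is an independently simulated spike train of `window_ms`
#' duration, emulating fixed-length task windows (e.g. 1000 ms hold periods).
#' Spike history never crosses rows.
#'
#' @param params a [sim_params()] object (its `T` field is ignored).
#' @param n_trials number of rows.
#' @param window_ms window duration in ms (default 1000).
#' @param seed optional integer seed.
#' @return a `trial_matrix` object: an `n_trials x window_ms` binary matrix.
#' @export
simulate_trial_matrix <- function(params, n_trials, window_ms = 1000,
                                  seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  stopifnot(n_trials >= 0, window_ms >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0L, nrow = n_trials, ncol = window_ms)
  for (i in seq_len(n_trials)) {
    m[i, ] <- cpp_simulate_train(as.integer(window_ms),
                                 params$p_base / 1000, params$p_osc / 1000,
                                 params$f_osc, params$n_r, params$k)
  }
  structure(m, class = c("trial_matrix", "matrix", "array"))
}

#' Matched non-bursty reference presets
#'
#' Named parameter sets for simulating reference spike trains matched to two
#' recorded thalamic (VLa) units with suspected burst firing: the same
#' duration, oscillation frequency and base rate, but no bursting component
#' and a 1 ms absolute recovery period.
#'
#' * `"vla1"`: `T = 118 * 1024` ms, `f_osc = 13` Hz, `p_base = 15` Hz
#' * `"vla2"`: `T = 51 * 1024` ms, `f_osc = 14` Hz, `p_base = 21` Hz
#'
#' Both use `m = 0.6`, `n_r = 1`, `k = 0`.
#'
#' @param preset preset name, `"vla1"` or `"vla2"`.
#' @return a [sim_params()] object.
#' @export
reference_preset <- function(preset) {
  presets <- list(
    vla1 = list(T = 118L * 1024L, f_osc = 13, p_base = 15),
    vla2 = list(T = 51L * 1024L, f_osc = 14, p_base = 21))
  if (!is.character(preset) || length(preset) != 1L ||
      !preset %in% names(presets))
    stop("unknown reference preset: ", paste(preset, collapse = ", "),
         " (available: ", paste(names(presets), collapse = ", "), ")")
  p <- presets[[preset]]
  sim_params(p_base = p$p_base, f_osc = p$f_osc, m = 0.6, n_r = 1, k = 0,
             T = p$T)
}

#' Simulate a matched non-bursty reference train
#'
#' Convenience wrapper around [simulate_spike_train()] using the
#' [reference_preset()] parameter sets.
#'
#' @param preset preset name (see [reference_preset()]).
#' @param seed optional integer seed.
#' @return a `spike_train` object.
#' @export
simulate_reference_train <- function(preset, seed = NULL) {
  simulate_spike_train(reference_preset(preset), seed = seed)
}
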