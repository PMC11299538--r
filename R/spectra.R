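#' The standard 513-point frequency grid
#'
#' Welch segments are 1024 ms at 1 kHz, so one-sided spectra live on 513
#' frequencies `i * 1000/1024` Hz, `i = 0..512`, spanning `[0, 500]` Hz with a
#' resolution of about 0.9766 Hz. Bins are labeled by their exact grid
#' frequency (lower bound): 0.9766, 1.9531, 2.9297, ...
#'
#' @return numeric vector of 513 frequencies in Hz.
#' @export
psd_frequencies <- function() {
  (0:512) * (1000 / 1024)
}

new_psd <- function(power, n_segments) {
  stopifnot(length(power) == 513L)
  structure(list(freq = psd_frequencies(), power = as.numeric(power),
                 n_segments = as.integer(n_segments)),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("psd: 513 bins on [0, 500] Hz, %d segment(s)\n", x$n_segments))
  invisible(x)
}

#' Welch power spectral density of a 1 kHz series
#'
#' Splits the input into non-overlapping 1024-sample segments, optionally
#' demeans each, applies a symmetric Hamming taper, and averages the one-sided
#' periodograms (the `pwelch` convention: density scaled by
#' `fs * sum(w^2)`, doubled except at DC and Nyquist). Spike trains (delta
#' vectors) and residual series are both accepted.
#'
#' @param x numeric vector whose length is a positive multiple of 1024, or a
#'   `spike_train`.
#' @param demean_per_segment demean each segment before tapering (default
#'   `TRUE`). Set `FALSE` when segments were already demeaned upstream, as in
#'   the windowed-data conventions.
#' @return a `psd` object.
#' @examples
#' p <- welch_psd(simulate_spike_train(sim_params(p_base = 30, T = 10240),
#'                                     seed = 1))
#' @export
welch_psd <- function(x, demean_per_segment = TRUE) {
  if (inherits(x, "spike_train")) x <- x$delta
  x <- as.numeric(x)
  if (length(x) == 0L || length(x) %% 1024L != 0L)
    stop("length of x must be a positive multiple of 1024")
  new_psd(cpp_welch_psd(x, isTRUE(demean_per_segment)),
          length(x) %/% 1024L)
}

#' Welch PSD of trial-windowed data
#'
#' Each row (one task window) is demeaned, zero-padded on the right to
#' 1024 ms, and treated as one Welch segment; per-segment demeaning in the
#' spectral stage is disabled so the padding is preserved.
#'
#' @param trials a `trial_matrix` (rows = trials) or plain binary matrix.
#' @param pad_ms zero padding per row; `ncol(trials) + pad_ms` must equal
#'   1024 (default 24 for 1000 ms windows).
#' @return a `psd` object with `n_segments = nrow(trials)`.
#' @export
welch_psd_windowed <- function(trials, pad_ms = 1024L - ncol(trials)) {
  trials <- as.matrix(trials)
  if (nrow(trials) < 1L) stop("need at least one trial window")
  if (ncol(trials) + pad_ms != 1024L)
    stop("row length + pad_ms must equal 1024 (got ",
         ncol(trials), " + ", pad_ms, ")")
  segs <- matrix(0, nrow = 1024L, ncol = nrow(trials))
  w <- ncol(trials)
  for (i in seq_len(nrow(trials))) {
    row <- as.numeric(trials[i, ])
    segs[seq_len(w), i] <- row - mean(row)
  }
  new_psd(cpp_psd_from_segments(segs), nrow(trials))
}

hf_band_idx <- function(freq) which(freq >= 250 & freq <= 500)
search_band_idx <- function(freq) which(freq > 0 & freq <= 100)

#' High-frequency-derived significance test
#'
#' Labels points of a spectrum in the (0, 100] Hz search range (102 bins) as
#' significant when their power strictly exceeds the upper limit of a
#' one-sided confidence interval built from the mean and SD of the same
#' spectrum over [250, 500] Hz, where spectra of a 1 kHz point process are
#' flat apart from noise. The family-wise level `alpha_c` is Bonferroni-split
#' over the 102 candidate bins:
#' `threshold = hf_mean + qnorm(1 - alpha_c/102) * hf_sd`.
#'
#' @param psd a `psd` object on the standard grid.
#' @param alpha_c family-wise significance level (default 0.05).
#' @return a `significance_result` with fields `alpha_c`, `threshold`,
#'   `hf_mean`, `hf_sd`, `freq` (the 102 searched labels) and `sig` (logical).
#' @export
significance_test <- function(psd, alpha_c = 0.05) {
  stopifnot(inherits(psd, "psd"))
  if (!is.numeric(alpha_c) || length(alpha_c) != 1L ||
      alpha_c <= 0 || alpha_c > 1)
    stop("alpha_c must lie in (0, 1]")
  hf <- psd$power[hf_band_idx(psd$freq)]
  if (length(hf) < 2L) stop("too few high-frequency bins to form the CI")
  hf_mean <- mean(hf)
  hf_sd <- sd(hf)
  idx <- search_band_idx(psd$freq)
  z <- qnorm(1 - alpha_c / length(idx))
  threshold <- hf_mean + z * hf_sd
  structure(
    list(alpha_c = alpha_c, threshold = threshold,
         hf_mean = hf_mean, hf_sd = hf_sd,
         freq = psd$freq[idx], sig = psd$power[idx] > threshold),
    class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf(
    "significance_result: alpha_c=%g, threshold=%.4g, %d/%d bins significant\n",
    x$alpha_c, x$threshold, sum(x$sig), length(x$sig)))
  if (any(x$sig))
    cat("  at:", paste(sprintf("%.4f", x$freq[x$sig]), collapse = ", "),
        "Hz\n")
  invisible(x)
}

#' Pointwise ratio of two spectra
#'
#' Divides a spectrum by a control spectrum on the same grid (the
#' shuffling-correction step). `0/0` is defined as 1 by convention; a zero
#' control bin under nonzero original power is an error.
#'
#' @param psd_orig,psd_control `psd` objects on identical grids.
#' @return a `psd` object holding the ratio.
#' @export
corrected_ratio <- function(psd_orig, psd_control) {
  stopifnot(inherits(psd_orig, "psd"), inherits(psd_control, "psd"))
  if (!isTRUE(all.equal(psd_orig$freq, psd_control$freq)))
    stop("spectra are not on the same frequency grid")
  a <- psd_orig$power
  b <- psd_control$power
  bad <- b == 0 & a != 0
  if (any(bad))
    stop("control spectrum is zero at ", sum(bad),
         " bin(s) with nonzero original power")
  r <- ifelse(a == 0 & b == 0, 1, a / b)
  new_psd(r, psd_orig$n_segments)
}
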