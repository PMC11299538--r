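#' Globally ISI-shuffled surrogate of an unbroken spike train
#'
#' Randomly permutes all inter-spike intervals of the train. The first spike
#' stays anchored at its original bin and the permuted ISIs are appended
#' after it, so the spike count and the ISI multiset are conserved exactly.
#' Such surrogates estimate the renewal-equivalent process implied by the
#' first-order ISI statistics alone.
#'
#' @param train a `spike_train`.
#' @return a `spike_train` surrogate. With fewer than 2 spikes there are no
#'   ISIs to permute: the input is returned with a warning.
#' @export
global_shuffle <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  st <- spike_times(train)
  if (length(st) < 2L) {
    warning("fewer than 2 spikes: no ISIs to permute, returning input")
    return(train)
  }
  isis <- diff(st)
  perm <- if (length(isis) == 1L) isis else sample(isis)
  new_times <- st[1L] + cumsum(c(0L, perm))
  spike_train_from_times(new_times, length(train$delta))
}

#' Shuffling-corrected PSD of an unbroken spike train
#'
#' Generates `n_surrogates` globally ISI-shuffled surrogates, averages their
#' segment-demeaned Welch spectra into a control (renewal-equivalent) PSD,
#' and divides the original PSD by it.
#'
#' @param train a `spike_train` whose length is a multiple of 1024.
#' @param n_surrogates number of surrogates (default 100).
#' @return a list of class `corrected_psd` with elements `corrected`,
#'   `control`, `original` (all `psd`), `method = "shuffling"` and
#'   `n_surrogates`.
#' @export
shuffling_corrected_psd <- function(train, n_surrogates = 100L) {
  stopifnot(inherits(train, "spike_train"))
  original <- welch_psd(train$delta, demean_per_segment = TRUE)
  st <- spike_times(train)
  if (length(st) < 2L)
    stop("need at least 2 spikes to form ISI-shuffled surrogates")
  control <- new_psd(
    cpp_shuffle_mean_psd(st, length(train$delta), as.integer(n_surrogates)),
    original$n_segments)
  structure(
    list(corrected = corrected_ratio(original, control),
         control = control, original = original,
         method = "shuffling", n_surrogates = as.integer(n_surrogates)),
    class = "corrected_psd")
}

#' @export
print.corrected_psd <- function(x, ...) {
  cat(sprintf("corrected_psd (%s): %d segment(s)\n",
              x$method, x$original$n_segments))
  invisible(x)
}

#' Global ISI shuffling for trial-windowed data
#'
#' Extends global ISI shuffling to temporally separated fixed-length windows.
#' All within-row ISIs are pooled and sorted in descending order (a
#' max-oriented priority queue), then placed greedily: each ISI goes to a
#' uniformly chosen row that still has room (initial room `W - 1` ms, one bin
#' reserved for the row's first spike), packed left-aligned. Finally the ISIs
#' within each row are randomly re-sequenced and the row's spikes are
#' right-shifted by a uniform draw from `{0, ..., timeLeft}`. The pooled ISI
#' multiset is conserved exactly; the total spike count may differ from the
#' input (one first spike per row that received any ISI).
#'
#' @param trials a `trial_matrix` or binary matrix (rows = trials).
#' @return a shuffled matrix of the same shape. A matrix with no within-row
#'   ISIs is returned unchanged (all zeros in, all zeros out). If some ISI
#'   cannot be placed in any row the function errors, naming the ISI; a retry
#'   with a different RNG state may succeed.
#' @export
windowed_global_shuffle <- function(trials) {
  trials <- as.matrix(trials)
  nD <- nrow(trials)
  W <- ncol(trials)
  isis <- integer(0)
  for (i in seq_len(nD)) {
    st <- which(trials[i, ] != 0)
    if (length(st) >= 2L) isis <- c(isis, diff(st))
  }
  out <- matrix(0L, nD, W)
  if (length(isis) == 0L) return(structure(out, class = class(trials)))
  s_isi <- sort(isis, decreasing = TRUE)
  time_left <- rep(W - 1L, nD)
  last_spike <- integer(nD)          # rightmost spike col, 0 = empty row
  for (isi in s_isi) {
    open <- which(time_left >= isi)
    if (length(open) == 0L)
      stop("no row has room left for an ISI of ", isi,
           " ms; retry with a different RNG state")
    row <- if (length(open) == 1L) open else sample(open, 1L)
    if (last_spike[row] == 0L) {
      out[row, 1L] <- 1L
      out[row, 1L + isi] <- 1L
      last_spike[row] <- 1L + isi
    } else {
      out[row, last_spike[row] + isi] <- 1L
      last_spike[row] <- last_spike[row] + isi
    }
    time_left[row] <- time_left[row] - isi
  }
  for (i in seq_len(nD)) {
    st <- which(out[i, ] != 0)
    if (length(st) > 2L) {          # re-sequence the row's ISIs
      perm <- sample(diff(st))
      st <- st[1L] + cumsum(c(0L, perm))
      out[i, ] <- 0L
      out[i, st] <- 1L
    }
    if (time_left[i] > 0L && length(st) > 0L) {
      shift <- sample.int(time_left[i] + 1L, 1L) - 1L
      if (shift > 0L) {
        out[i, ] <- 0L
        out[i, st + shift] <- 1L
      }
    }
  }
  structure(out, class = class(trials))
}

#' Shuffling-corrected PSD for trial-windowed data
#'
#' As [shuffling_corrected_psd()], but surrogates come from
#' [windowed_global_shuffle()] and spectra from [welch_psd_windowed()].
#' Because greedy placement can rarely fail, each surrogate is retried up to
#' `max_retries` times with fresh RNG draws before erroring.
#'
#' @param trials a `trial_matrix`.
#' @param n_surrogates number of surrogates (default 100).
#' @param max_retries placement retries per surrogate (default 10).
#' @return a `corrected_psd` list (see [shuffling_corrected_psd()]).
#' @export
shuffling_corrected_psd_windowed <- function(trials, n_surrogates = 100L,
                                             max_retries = 10L) {
  trials <- as.matrix(trials)
  n_isi <- sum(pmax(rowSums(trials != 0) - 1L, 0L))
  if (n_isi < 1L)
    stop("trial matrix contains no within-row ISIs to shuffle")
  original <- welch_psd_windowed(trials)
  acc <- numeric(513L)
  for (s in seq_len(n_surrogates)) {
    surr <- NULL
    for (r in seq_len(max_retries)) {
      surr <- tryCatch(windowed_global_shuffle(trials),
                       error = function(e) NULL)
      if (!is.null(surr)) break
    }
    if (is.null(surr))
      stop("windowed shuffle failed after ", max_retries, " retries")
    acc <- acc + welch_psd_windowed(surr)$power
  }
  control <- new_psd(acc / n_surrogates, original$n_segments)
  structure(
    list(corrected = corrected_ratio(original, control),
         control = control, original = original,
         method = "shuffling", n_surrogates = as.integer(n_surrogates)),
    class = "corrected_psd")
}
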