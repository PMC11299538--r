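#' The standard significance-threshold grid for ROC analysis
#'
#' The 17 family-wise levels `sort(c(1, 5) * 10^(-8..-1))` together with 1.
#'
#' @return increasing numeric vector of length 17.
#' @export
alpha_grid <- function() {
  sort(c(as.vector(outer(c(1, 5), 10^(-8:-1))), 1))
}

#' Frequency bins eligible as hits or false alarms
#'
#' Hit bins are the 3 nearest neighbors of `f_osc` among the 102 searched
#' labels (ties toward lower frequency); false-alarm bins are those more
#' than 5 Hz from `f_osc` (equivalently, outside its 10 nearest neighbors).
#'
#' @param f_osc oscillation frequency in Hz, inside (0, 100].
#' @return list with integer index vectors `hit` and `fa` into the 102
#'   searched bins.
#' @export
detection_bins <- function(f_osc) {
  freq <- psd_frequencies()
  labels <- freq[freq > 0 & freq <= 100]
  d <- abs(labels - f_osc)
  list(hit = sort(order(d)[1:3]), fa = which(d > 5))
}

#' Classify one corrected PSD as hit / false alarm
#'
#' A PSD counts as a hit when the train was simulated with `m > 0` and any
#' of the 3 grid bins nearest `f_osc` is significant. It counts as a false
#' alarm when `m = 0` and any searched bin is significant, or `m > 0` and
#' any bin farther than 5 Hz from `f_osc` is significant.
#'
#' @param sig a `significance_result` over the standard 102-bin search grid.
#' @param f_osc ground-truth oscillation frequency in Hz.
#' @param m ground-truth modulation index.
#' @return list of class `detection_label` with logical fields `hit`, `fa`.
#' @export
classify_psd <- function(sig, f_osc, m) {
  stopifnot(inherits(sig, "significance_result"))
  if (length(sig$sig) != 102L)
    stop("significance result is not on the standard 102-bin search grid")
  if (m > 0 && (f_osc <= 0 || f_osc > 100))
    stop("f_osc must lie in (0, 100] when m > 0")
  if (m > 0) {
    b <- detection_bins(f_osc)
    hit <- any(sig$sig[b$hit])
    fa <- any(sig$sig[b$fa])
  } else {
    hit <- FALSE
    fa <- any(sig$sig)
  }
  structure(list(hit = hit, fa = fa), class = "detection_label")
}

# Scale-free summary of one PSD for threshold sweeps: the largest
# standardized exceedance (power - hf_mean)/hf_sd over the hit and FA bin
# sets. hit/FA at level alpha <=> zmax > qnorm(1 - alpha/102), matching the
# strict-inequality convention of significance_test().
psd_zmax <- function(psd, f_osc, m) {
  hf <- psd$power[hf_band_idx(psd$freq)]
  hf_mean <- mean(hf)
  hf_sd <- sd(hf)
  sidx <- search_band_idx(psd$freq)
  p <- psd$power[sidx]
  z <- if (hf_sd > 0) (p - hf_mean) / hf_sd
       else ifelse(p > hf_mean, Inf, -Inf)
  if (m > 0) {
    b <- detection_bins(f_osc)
    c(zmax_hit = max(z[b$hit]), zmax_fa = max(z[b$fa]))
  } else {
    c(zmax_hit = -Inf, zmax_fa = max(z))
  }
}

#' Grid configuration for method evaluation
#'
#' Declares a factorial grid of simulation settings. `p_base` is set either
#' directly (`p_base` entry) or as `f_osc + p_base_offset` (the sparseness
#' control used by the primary synthetic dataset).
#'
#' @param T spike-train durations, ms (multiples of 1024).
#' @param f_osc oscillation frequencies, Hz.
#' @param p_base_offset offsets added to `f_osc` to obtain `p_base`, Hz
#'   (exclusive with `p_base`).
#' @param p_base base rates, Hz (exclusive with `p_base_offset`).
#' @param m modulation indices in `[0, 1]`.
#' @param n_r,k recovery-period duration (ms) and steepness.
#' @param reps simulated trains per cell.
#' @param seed base RNG seed; per-train seeds are derived deterministically.
#' @param n_surrogates shuffling surrogates per train.
#' @param methods correction methods to run.
#' @return a `grid_config` list, with the expanded cell table in `$cells`.
#' @export
grid_config <- function(T, f_osc, p_base_offset = NULL, p_base = NULL,
                        m, n_r = 9L, k = 0.7, reps = 100L, seed = 1L,
                        n_surrogates = 100L,
                        methods = c("residuals", "shuffling"),
                        skip_m0_methods = FALSE) {
  if (is.null(p_base_offset) == is.null(p_base))
    stop("supply exactly one of p_base_offset or p_base")
  if (any(m < 0 | m > 1)) stop("m must lie in [0, 1]")
  if (any(T %% 1024 != 0)) stop("all T must be multiples of 1024")
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(p_base)) {
    cells <- expand.grid(T = as.integer(T), f_osc = f_osc,
                         p_base_offset = p_base_offset, m = m,
                         KEEP.OUT.ATTRS = FALSE)
    cells$p_base <- cells$f_osc + cells$p_base_offset
  } else {
    cells <- expand.grid(T = as.integer(T), f_osc = f_osc,
                         p_base = p_base, m = m, KEEP.OUT.ATTRS = FALSE)
    cells$p_base_offset <- cells$p_base - cells$f_osc
  }
  cells$cell <- seq_len(nrow(cells))
  structure(list(cells = cells, n_r = as.integer(n_r), k = k,
                 reps = as.integer(reps), seed = as.integer(seed),
                 n_surrogates = as.integer(n_surrogates),
                 methods = methods,
                 skip_m0_methods = isTRUE(skip_m0_methods)),
            class = "grid_config")
}

#' The primary synthetic evaluation grid
#'
#' 540 cells: `T` in {30, 60, 120} x 1024 ms, `f_osc` in {7, 9, 12, 20, 32}
#' Hz, `p_base = f_osc + 2^(0:5)` Hz, `m` in {0, 0.2, ..., 1}, with the
#' default 9 ms / k = 0.7 recovery period.
#'
#' @param reps trains per cell (100 at full scale; reducible).
#' @param seed base RNG seed.
#' @param n_r,k recovery-period settings (defaults 9 ms, 0.7; set
#'   `n_r = 3, k = 0` for the short absolute-RP variant).
#' @return a `grid_config`.
#' @export
primary_grid <- function(reps = 100L, seed = 1L, n_r = 9L, k = 0.7) {
  grid_config(T = c(30, 60, 120) * 1024, f_osc = c(7, 9, 12, 20, 32),
              p_base_offset = 2^(0:5), m = seq(0, 1, by = 0.2),
              n_r = n_r, k = k, reps = reps, seed = seed)
}

#' Run a simulation grid through both correction methods
#'
#' For every cell and repetition: simulate a train, estimate the recovery
#' period, compute the shuffling- and residuals-corrected PSDs, and record
#' the standardized peak exceedances over the hit- and FA-eligible bins
#' (from which hit/false-alarm labels at any `alpha_c` follow; see
#' [label_table()]). Per-train failures are recorded as `NA`, not fatal.
#' Per-train seeds are `seed + train index` (mod 2^31), so grids are
#' reproducible and extensible.
#'
#' @param config a `grid_config`. Set its `skip_m0_methods` element to
#'   `TRUE` to skip the PSD methods on `m = 0` cells (recovery-period
#'   estimates are still recorded there), which matters only for rate
#'   summaries restricted to `m > 0` cells.
#' @param rp_only skip the PSD methods and record only recovery-period
#'   estimates (used for RP-accuracy summaries).
#' @param progress print one line per 100 trains.
#' @return a `grid_results` data.frame with one row per train x method (or
#'   per train when `rp_only`): cell parameters, `rep`, `n_r_hat`, `method`,
#'   `zmax_hit`, `zmax_fa`.
#' @export
run_grid <- function(config, rp_only = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "grid_config"))
  cells <- config$cells
  reps <- config$reps
  out <- vector("list", nrow(cells) * reps)
  idx <- 0L
  skip_m0 <- isTRUE(config$skip_m0_methods)
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    run_methods <- if (rp_only || (skip_m0 && cell$m == 0)) character(0)
                   else config$methods
    params <- sim_params(p_base = cell$p_base, f_osc = cell$f_osc,
                         m = cell$m, n_r = config$n_r, k = config$k,
                         T = cell$T)
    for (r in seq_len(reps)) {
      idx <- idx + 1L
      seed <- (config$seed + idx) %% .Machine$integer.max
      train <- simulate_spike_train(params, seed = seed)
      n_r_hat <- tryCatch(
        estimate_rp_duration(train)$n_r_hat,
        error = function(e) NA_integer_)
      rec0 <- data.frame(cell = cell$cell, T = cell$T, f_osc = cell$f_osc,
                         p_base = cell$p_base,
                         p_base_offset = cell$p_base_offset,
                         m = cell$m, rep = r, seed = seed,
                         n_r_hat = n_r_hat)
      recs <- list()
      if (rp_only || length(run_methods) == 0L) {
        rec0$method <- NA_character_
        rec0$zmax_hit <- NA_real_
        rec0$zmax_fa <- NA_real_
        recs <- list(rec0)
      } else {
        for (meth in run_methods) {
          rec <- rec0
          rec$method <- meth
          zz <- tryCatch(suppressWarnings({
            psd <- if (meth == "residuals") {
              if (is.na(n_r_hat)) stop("no RP estimate")
              residuals_corrected_psd(train, n_r_hat = n_r_hat)$psd
            } else {
              shuffling_corrected_psd(train, config$n_surrogates)$corrected
            }
            psd_zmax(psd, cell$f_osc, cell$m)
          }), error = function(e) c(zmax_hit = NA_real_, zmax_fa = NA_real_))
          rec$zmax_hit <- zz[["zmax_hit"]]
          rec$zmax_fa <- zz[["zmax_fa"]]
          recs[[length(recs) + 1L]] <- rec
        }
      }
      out[[idx]] <- do.call(rbind, recs)
      if (progress && idx %% 100L == 0L)
        message("run_grid: ", idx, " / ", nrow(cells) * reps, " trains")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "config") <- config
  class(res) <- c("grid_results", class(res))
  res
}

#' Expand grid results into per-threshold hit/false-alarm labels
#'
#' One row per train x method x `alpha_c` with logical `hit` and `fa`
#' columns, using the same strict-exceedance rule as [significance_test()].
#'
#' @param results a `grid_results` table.
#' @param alpha vector of family-wise levels (default [alpha_grid()]).
#' @return a data.frame.
#' @export
label_table <- function(results, alpha = alpha_grid()) {
  res <- results[!is.na(results$method), , drop = FALSE]
  n <- nrow(res)
  out <- res[rep(seq_len(n), each = length(alpha)),
             c("cell", "T", "f_osc", "p_base_offset", "m", "rep", "method")]
  out$alpha_c <- rep(alpha, times = n)
  zc <- qnorm(1 - out$alpha_c / 102)
  out$hit <- (out$m > 0) &
    rep(res$zmax_hit, each = length(alpha)) > zc
  out$fa <- rep(res$zmax_fa, each = length(alpha)) > zc
  out$hit[is.na(out$hit)] <- NA
  rownames(out) <- NULL
  out
}

#' Subsampled ROC curves for the correction methods
#'
#' Draws `n_subsamples` subsamples of `per_cell` trains (without
#' replacement) from every `m > 0` cell, and for each subsample and method
#' forms the hit-rate and false-alarm-rate curves over the `alpha` grid,
#' pooled across the drawn trains. Trains for which either method failed are
#' excluded pairwise so the comparison stays paired.
#'
#' @param results a `grid_results` table from [run_grid()].
#' @param n_subsamples number of bootstrap subsamples (default 1000).
#' @param per_cell trains drawn per cell (default 20); must not exceed the
#'   available reps.
#' @param seed optional RNG seed.
#' @param alpha threshold grid (default [alpha_grid()]).
#' @return a `roc_curves` object: list with `alpha`, `methods`, and arrays
#'   `hr`, `fa` of dim `(n_subsamples, n_methods, n_alpha)`.
#' @export
subsample_roc <- function(results, n_subsamples = 1000L, per_cell = 20L,
                          seed = NULL, alpha = alpha_grid()) {
  if (!is.null(seed)) set.seed(seed)
  res <- results[!is.na(results$method) & results$m > 0, , drop = FALSE]
  methods <- sort(unique(res$method))
  # pairwise-complete trains only
  key <- paste(res$cell, res$rep)
  ok_key <- tapply(!is.na(res$zmax_fa), key, all)
  res <- res[ok_key[key], , drop = FALSE]
  cells <- unique(res$cell)
  per_cell <- as.integer(per_cell)
  avail <- tapply(res$rep[res$method == methods[1L]],
                  res$cell[res$method == methods[1L]], length)
  if (any(avail < per_cell))
    stop("per_cell = ", per_cell, " exceeds available trains in some cell")
  zc <- qnorm(1 - alpha / 102)
  hr <- array(NA_real_, c(n_subsamples, length(methods), length(alpha)))
  fa <- array(NA_real_, c(n_subsamples, length(methods), length(alpha)))
  split_by_cell <- split(seq_len(nrow(res)), res$cell)
  rep_of <- res$rep
  for (s in seq_len(n_subsamples)) {
    take <- logical(nrow(res))
    for (cl in cells) {
      ridx <- split_by_cell[[as.character(cl)]]
      reps_avail <- unique(rep_of[ridx])
      chosen <- if (length(reps_avail) == per_cell) reps_avail
                else sample(reps_avail, per_cell)
      take[ridx[rep_of[ridx] %in% chosen]] <- TRUE
    }
    sub <- res[take, , drop = FALSE]
    for (mi in seq_along(methods)) {
      sm <- sub[sub$method == methods[mi], , drop = FALSE]
      for (ai in seq_along(alpha)) {
        hr[s, mi, ai] <- mean(sm$zmax_hit > zc[ai])
        fa[s, mi, ai] <- mean(sm$zmax_fa > zc[ai])
      }
    }
  }
  structure(list(alpha = alpha, methods = methods, hr = hr, fa = fa),
            class = "roc_curves")
}

# Area under the piecewise-linear (fa, hr) curve cropped to [lo, hi].
# Points are taken in threshold order (fa and hr both nondecreasing), so
# runs of tied fa are vertical segments contributing zero width; each
# segment is clipped to the crop with linear interpolation and the clipped
# polyline integrated by the trapezoidal rule.
pauc_trapz <- function(fa, hr, lo, hi) {
  o <- order(fa, hr)
  fa <- fa[o]
  hr <- hr[o]
  xs <- numeric(0)
  ys <- numeric(0)
  for (i in seq_len(length(fa) - 1L)) {
    x1 <- fa[i]
    x2 <- fa[i + 1L]
    if (x2 <= lo || x1 >= hi || x1 == x2) next
    a <- max(x1, lo)
    b <- min(x2, hi)
    yl <- hr[i] + (hr[i + 1L] - hr[i]) * (a - x1) / (x2 - x1)
    yr <- hr[i] + (hr[i + 1L] - hr[i]) * (b - x1) / (x2 - x1)
    xs <- c(xs, a, b)
    ys <- c(ys, yl, yr)
  }
  if (length(xs) == 0L) return(0)
  pracma::trapz(xs, ys)
}

#' Partial-AUC comparison of two correction methods
#'
#' Crops every ROC curve to the intersection of all curves' false-alarm
#' ranges, integrates each cropped curve by the trapezoidal rule, and
#' paired-t-tests the per-subsample pAUC difference
#' (first method listed alphabetically last), i.e.
#' `D = pAUC[residuals] - pAUC[shuffling]` for the standard pair.
#'
#' @param roc a `roc_curves` object from [subsample_roc()].
#' @return list with `fa_range`, matrix `pauc` (subsample x method),
#'   `d_pauc` (per-subsample difference), `mean_d`, `t`, `p`. With zero
#'   variance in the differences the t statistic is undefined and reported
#'   as `NA` (no detectable difference).
#' @export
pauc_compare <- function(roc) {
  stopifnot(inherits(roc, "roc_curves"))
  ns <- dim(roc$hr)[1L]
  if (ns < 2L) stop("need at least 2 subsamples")
  lo <- max(apply(roc$fa, c(1, 2), min))
  hi <- min(apply(roc$fa, c(1, 2), max))
  if (hi <= lo)
    stop("empty common false-alarm interval [", lo, ", ", hi, "]")
  pauc <- matrix(NA_real_, ns, length(roc$methods),
                 dimnames = list(NULL, roc$methods))
  for (s in seq_len(ns))
    for (mi in seq_along(roc$methods))
      pauc[s, mi] <- pauc_trapz(roc$fa[s, mi, ], roc$hr[s, mi, ], lo, hi)
  if (all(c("residuals", "shuffling") %in% roc$methods)) {
    d <- pauc[, "residuals"] - pauc[, "shuffling"]
  } else {
    d <- pauc[, 1L] - pauc[, ncol(pauc)]
  }
  if (sd(d) > 0) {
    tt <- t.test(d)
    tstat <- unname(tt$statistic)
    pval <- tt$p.value
  } else {
    tstat <- NA_real_
    pval <- NA_real_
  }
  list(fa_range = c(lo, hi), pauc = pauc, d_pauc = d,
       mean_d = mean(d), t = tstat, p = pval)
}

#' Mean hit and false-alarm rates at a fixed threshold
#'
#' Convenience summary: hit and FA rates per method at one `alpha_c`,
#' averaged over subsampled ROC draws (matching the bootstrapped rate
#' summaries reported for grid evaluations).
#'
#' @param roc a `roc_curves` object.
#' @param alpha_c threshold to report (must be on the curve grid).
#' @return data.frame with `method`, `hit_rate`, `fa_rate` in percent.
#' @export
rate_summary <- function(roc, alpha_c = 0.05) {
  ai <- which(abs(roc$alpha - alpha_c) < 1e-12)
  if (length(ai) != 1L) stop("alpha_c not on the curve grid")
  hm <- matrix(roc$hr[, , ai], ncol = length(roc$methods))
  fm <- matrix(roc$fa[, , ai], ncol = length(roc$methods))
  data.frame(method = roc$methods,
             hit_rate = 100 * colMeans(hm),
             fa_rate = 100 * colMeans(fm))
}

#' False-alarm peak-power descriptives
#'
#' For each corrected PSD containing both significant hit-eligible and
#' significant FA-eligible points at level `alpha_c`, computes the ratio of
#' the peak (maximum) power over the FA points to the peak power over the
#' hit points, and the frequency of the FA peak. PSDs lacking either kind of
#' point are excluded.
#'
#' @param psds list of `psd` objects.
#' @param f_osc,m ground-truth parameters, recycled across `psds`.
#' @param alpha_c significance level (default 0.05).
#' @return list with per-PSD `table` (`ratio`, `peak_fa_freq`) and summary
#'   means `mean_ratio`, `mean_peak_fa_freq`, `n`. Empty when no PSD
#'   qualifies.
#' @export
fa_descriptives <- function(psds, f_osc, m, alpha_c = 0.05) {
  n <- length(psds)
  f_osc <- rep_len(f_osc, n)
  m <- rep_len(m, n)
  rows <- list()
  for (i in seq_len(n)) {
    sig <- significance_test(psds[[i]], alpha_c)
    if (m[i] <= 0) next              # ratio needs a defined hit zone
    b <- detection_bins(f_osc[i])
    sidx <- search_band_idx(psds[[i]]$freq)
    p <- psds[[i]]$power[sidx]
    hit_sig <- b$hit[sig$sig[b$hit]]
    fa_sig <- b$fa[sig$sig[b$fa]]
    if (length(hit_sig) == 0L || length(fa_sig) == 0L) next
    ratio <- max(p[fa_sig]) / max(p[hit_sig])
    peak_fa <- sig$freq[fa_sig[which.max(p[fa_sig])]]
    rows[[length(rows) + 1L]] <- data.frame(psd = i, ratio = ratio,
                                            peak_fa_freq = peak_fa)
  }
  if (length(rows) == 0L)
    return(list(table = data.frame(psd = integer(0), ratio = numeric(0),
                                   peak_fa_freq = numeric(0)),
                mean_ratio = NA_real_, mean_peak_fa_freq = NA_real_, n = 0L))
  tab <- do.call(rbind, rows)
  list(table = tab, mean_ratio = mean(tab$ratio),
       mean_peak_fa_freq = mean(tab$peak_fa_freq), n = nrow(tab))
}
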