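make_sig <- function(sig_idx) {
  # minimal significance_result on the standard search grid
  freq <- psd_frequencies()
  labels <- freq[freq > 0 & freq <= 100]
  s <- logical(102)
  s[sig_idx] <- TRUE
  structure(list(alpha_c = 0.05, threshold = 1, hf_mean = 0, hf_sd = 1,
                 freq = labels, sig = s),
            class = "significance_result")
}

test_that("hit and FA bin sets follow the nearest-neighbor rules", {
  b <- detection_bins(12)
  labels <- psd_frequencies()[2:103]
  expect_equal(round(labels[b$hit], 4), c(10.7422, 11.7188, 12.6953))
  # FA set: > 5 Hz away, equivalently outside the 10 nearest neighbors
  ten_nearest <- order(abs(labels - 12))[1:10]
  expect_identical(sort(b$fa), sort(setdiff(seq_len(102),
                                            ten_nearest)))

  # brute-force agreement of the two FA formulations for many f_osc
  for (f in c(7, 9, 9.5, 20, 32, 48.83, 99)) {
    bb <- detection_bins(f)
    expect_identical(sort(bb$fa),
                     sort(which(abs(labels - f) > 5)))
  }
})

test_that("classify_psd implements the labeling contract", {
  # no significant bins: neither hit nor FA
  lab <- classify_psd(make_sig(integer(0)), f_osc = 9, m = 0.6)
  expect_false(lab$hit)
  expect_false(lab$fa)

  # single significant bin at 48.83 Hz with f_osc = 9: FA, not hit
  idx <- which.min(abs(psd_frequencies()[2:103] - 48.83))
  lab <- classify_psd(make_sig(idx), f_osc = 9, m = 0.6)
  expect_true(lab$fa)
  expect_false(lab$hit)

  # m = 0: any significance is an FA, hits impossible
  lab0 <- classify_psd(make_sig(50), f_osc = 9, m = 0)
  expect_true(lab0$fa)
  expect_false(lab0$hit)

  # hit at the nearest bin
  hit_idx <- detection_bins(9)$hit[1]
  labh <- classify_psd(make_sig(hit_idx), f_osc = 9, m = 0.6)
  expect_true(labh$hit)
  expect_false(labh$fa)

  expect_error(classify_psd(make_sig(1), f_osc = 150, m = 0.5), "f_osc")
})

test_that("run_grid bookkeeping matches the declared grid", {
  # the primary grid has 540 cells: 3 T x 5 f_osc x 6 offsets x 6 m
  pg <- primary_grid(reps = 1)
  expect_equal(nrow(pg$cells), 540L)
  expect_equal(pg$n_r, 9L)
  expect_equal(pg$k, 0.7)

  cfg <- grid_config(T = 4 * 1024, f_osc = 9, p_base_offset = 8, m = 0.6,
                     n_r = 9, k = 0.7, reps = 2, seed = 5,
                     n_surrogates = 10)
  res <- run_grid(cfg)
  expect_equal(nrow(res), 2L * 2L)       # 2 reps x 2 methods
  lab <- label_table(res)
  expect_equal(nrow(lab), 2L * 2L * 17L) # x 17 alpha levels
  expect_true(all(c("hit", "fa", "alpha_c") %in% names(lab)))

  # m = 0 rows are never hits at any threshold
  cfg0 <- grid_config(T = 4 * 1024, f_osc = 9, p_base_offset = 8, m = 0,
                      n_r = 9, k = 0.7, reps = 2, seed = 5,
                      n_surrogates = 10)
  lab0 <- label_table(run_grid(cfg0))
  expect_true(all(!lab0$hit))

  # same config, same seed: identical results
  res2 <- run_grid(cfg)
  expect_equal(res$zmax_hit, res2$zmax_hit)
})

test_that("alpha threshold grid and label expansion match the sweep rule", {
  a <- alpha_grid()
  expect_length(a, 17L)
  expect_equal(a[1], 1e-8)
  expect_equal(a[17], 1)
  expect_true(all(diff(a) > 0))

  # labels from label_table at alpha = 0.05 agree with classify_psd on the
  # real significance path
  p <- sim_params(p_base = 41, f_osc = 9, m = 0.6, n_r = 9, k = 0.7,
                  T = 30 * 1024)
  tr <- simulate_spike_train(p, seed = 9)
  out <- suppressWarnings(residuals_corrected_psd(tr))
  lab_direct <- classify_psd(significance_test(out$psd, 0.05), 9, 0.6)
  z <- rpspect:::psd_zmax(out$psd, 9, 0.6)
  zc <- qnorm(1 - 0.05 / 102)
  expect_identical(unname(z["zmax_hit"] > zc), lab_direct$hit)
  expect_identical(unname(z["zmax_fa"] > zc), lab_direct$fa)
})

test_that("subsampled ROC curves are monotone and correctly tallied", {
  # hand-built outcome table: 1 cell, 3 trains, known zmax values
  zc5 <- qnorm(1 - 0.05 / 102)   # ~3.72
  res <- data.frame(
    cell = 1L, T = 1024L, f_osc = 9, p_base = 17, p_base_offset = 8,
    m = 0.6, rep = rep(1:3, each = 2), seed = 1:6,
    n_r_hat = 9L,
    method = rep(c("residuals", "shuffling"), 3),
    zmax_hit = c(10, 2, 4, 10, -1, 2),
    zmax_fa = c(2, 10, -1, 3, 1, 8))
  class(res) <- c("grid_results", class(res))
  roc <- subsample_roc(res, n_subsamples = 4, per_cell = 3, seed = 1)
  # per_cell = reps: all subsamples identical (zero variance)
  expect_equal(apply(roc$hr, c(2, 3), function(x) diff(range(x))),
               matrix(0, 2, 17))
  # manual tally at alpha = 0.05: residuals hits = z > 3.72 -> {10, 4} / 3
  ai <- which(abs(roc$alpha - 0.05) < 1e-12)
  mi <- which(roc$methods == "residuals")
  expect_equal(roc$hr[1, mi, ai], 2 / 3)
  expect_equal(roc$fa[1, mi, ai], 0 / 3)
  ms <- which(roc$methods == "shuffling")
  expect_equal(roc$hr[1, ms, ai], 1 / 3)
  expect_equal(roc$fa[1, ms, ai], 2 / 3)
  # monotone nondecreasing in alpha on every curve
  for (mi in 1:2) {
    expect_true(all(diff(roc$hr[1, mi, ]) >= 0))
    expect_true(all(diff(roc$fa[1, mi, ]) >= 0))
  }
  expect_error(subsample_roc(res, n_subsamples = 2, per_cell = 5),
               "per_cell")
})

test_that("pAUC agrees with a fine-grid quadrature oracle", {
  # two hand-made piecewise-linear curves
  fa1 <- c(0.05, 0.1, 0.3, 0.6, 0.9)
  hr1 <- c(0.2, 0.5, 0.7, 0.9, 1.0)
  fa2 <- c(0.02, 0.15, 0.4, 0.7, 0.8)
  hr2 <- c(0.1, 0.3, 0.6, 0.8, 0.9)
  lo <- max(min(fa1), min(fa2))
  hi <- min(max(fa1), max(fa2))
  quad <- function(fa, hr, lo, hi, n = 2e5) {
    xs <- seq(lo, hi, length.out = n)
    ys <- approx(fa, hr, xout = xs)$y
    sum((ys[-1] + ys[-n]) / 2) * (hi - lo) / (n - 1)
  }
  got1 <- rpspect:::pauc_trapz(fa1, hr1, lo, hi)
  got2 <- rpspect:::pauc_trapz(fa2, hr2, lo, hi)
  expect_lt(abs(got1 - quad(fa1, hr1, lo, hi)), 1e-6)
  expect_lt(abs(got2 - quad(fa2, hr2, lo, hi)), 1e-6)
  # exact piecewise-linear areas, independent closed form
  exact <- function(fa, hr, lo, hi) {
    xs <- sort(unique(c(lo, hi, fa[fa > lo & fa < hi])))
    f <- function(x) approx(fa, hr, xout = x)$y
    sum(vapply(seq_len(length(xs) - 1), function(i)
      (f(xs[i]) + f(xs[i + 1])) / 2 * (xs[i + 1] - xs[i]), 0))
  }
  expect_lt(abs(got1 - exact(fa1, hr1, lo, hi)), 1e-10)
  expect_lt(abs(got2 - exact(fa2, hr2, lo, hi)), 1e-10)
})

test_that("pauc_compare reports no difference for identical methods", {
  res <- data.frame(
    cell = rep(1:2, each = 8),
    T = 1024L, f_osc = 9, p_base = 17, p_base_offset = 8, m = 0.6,
    rep = rep(rep(1:4, each = 2), 2), seed = 1,
    n_r_hat = 9L,
    method = rep(c("residuals", "shuffling"), 8),
    zmax_hit = rep(c(5, 5), 8),   # identical outcomes per train
    zmax_fa = rep(c(4, 4), 8))
  res$zmax_hit <- res$zmax_hit + rep(seq(0, 3.5, by = 0.5), each = 2)
  res$zmax_fa <- res$zmax_fa + rep(seq(-2, 1.5, by = 0.5), each = 2)
  class(res) <- c("grid_results", class(res))
  roc <- subsample_roc(res, n_subsamples = 5, per_cell = 3, seed = 2)
  cmp <- pauc_compare(roc)
  expect_true(all(cmp$d_pauc == 0))
  expect_true(is.na(cmp$t))
  expect_gte(min(cmp$pauc), 0)
  expect_lte(max(cmp$pauc), diff(cmp$fa_range) + 1e-12)
})

test_that("fa_descriptives computes peak ratios with exclusions", {
  # synthetic PSD with a hit peak of 10 and an FA peak of 2
  freq <- psd_frequencies()
  base <- rep(1, 513)
  hf_idx <- which(freq >= 250)
  psd_power <- base
  psd_power[hf_idx] <- 1            # hf mean 1, sd 0 -> threshold 1, strict
  hit_bin <- detection_bins(9)$hit[2] + 1L   # +1: search grid starts at bin 2
  fa_bin <- which(freq > 40 & freq <= 41)[1]
  psd_power[hit_bin] <- 10
  psd_power[fa_bin] <- 2
  psd <- rpspect:::new_psd(psd_power, 1L)
  out <- fa_descriptives(list(psd), f_osc = 9, m = 0.6)
  expect_equal(out$n, 1L)
  expect_equal(out$mean_ratio, 0.2)
  expect_equal(out$mean_peak_fa_freq, freq[fa_bin])

  # PSD with no FA bins is excluded
  psd2_power <- psd_power
  psd2_power[fa_bin] <- 1
  out2 <- fa_descriptives(list(rpspect:::new_psd(psd2_power, 1L)),
                          f_osc = 9, m = 0.6)
  expect_equal(out2$n, 0L)

  # brute-force scan agreement on a random significant spectrum
  set.seed(12)
  pw <- abs(rnorm(513, 5, 0.2))
  pw[sample(3:90, 6)] <- 9
  psd3 <- rpspect:::new_psd(pw, 1L)
  out3 <- fa_descriptives(list(psd3), f_osc = 30, m = 0.8)
  sig <- significance_test(psd3, 0.05)
  labels <- freq[2:103]
  sig_idx <- which(sig$sig)
  hits <- sig_idx[abs(labels[sig_idx] - 30) <=
                    max(abs(labels[detection_bins(30)$hit] - 30))]
  hits <- intersect(sig_idx, detection_bins(30)$hit)
  fas <- intersect(sig_idx, detection_bins(30)$fa)
  if (length(hits) && length(fas)) {
    expect_equal(out3$mean_ratio,
                 max(pw[fas + 1]) / max(pw[hits + 1]))
  } else {
    expect_equal(out3$n, 0L)
  }
})
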