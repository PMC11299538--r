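# Shared fixtures and independent oracles, built in code.

# long-run firing rate of the recovery-period renewal process (m = 0),
# by brute-force summation of the discrete survival function of the hazard
# sequence {p * k^(n_r+1-n)}_{n<=n_r} followed by p
renewal_rate_oracle <- function(p_base_hz, n_r, k, max_n = 100000L) {
  p <- p_base_hz / 1000
  n <- seq_len(max_n)
  h <- ifelse(n <= n_r, p * k^(n_r + 1 - n), p)
  surv <- cumprod(1 - h)
  s_prev <- c(1, surv[-max_n])
  pmf <- s_prev * h
  stopifnot(sum(pmf) > 1 - 1e-10)
  mean_isi <- sum(n * pmf)
  1000 / mean_isi
}

# direct-DFT Welch oracle (pwelch conventions), independent of the C++ path
direct_welch_oracle <- function(x, demean = TRUE) {
  nfft <- 1024L
  stopifnot(length(x) %% nfft == 0)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))
  nseg <- length(x) / nfft
  acc <- numeric(513)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1) * nfft + 1):(s * nfft)]
    if (demean) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[1:513]
    acc <- acc + Mod(X)^2
  }
  scale <- c(1, rep(2, 511), 1) / (1000 * sum(w^2))
  scale * acc / nseg
}

# a moderately dense oscillatory train used by several tests
fixture_train <- function(seed = 101, T = 30 * 1024, p_base = 41,
                          f_osc = 9, m = 0.4, n_r = 9, k = 0.7) {
  simulate_spike_train(
    sim_params(p_base = p_base, f_osc = f_osc, m = m, n_r = n_r, k = k,
               T = T),
    seed = seed)
}

# hand-rolled significance check used as an oracle against the package path
naive_significance <- function(power, alpha_c) {
  freq <- (0:512) * 1000 / 1024
  hf <- power[freq >= 250 & freq <= 500]
  thr <- mean(hf) + stats::qnorm(1 - alpha_c / 102) * stats::sd(hf)
  sig <- power[freq > 0 & freq <= 100] > thr
  sig
}
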