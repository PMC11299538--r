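// Hot paths: Eq.-style discrete-time spike simulation, Welch PSD of
// 1024-ms segments, and ISI-shuffle surrogate PSD averaging.
//
// All randomness goes through R's RNG (unif_rand / R_unif_index), so results
// are reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <Rmath.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const int NFFT = 1024;
static const int NBIN = 513;          // one-sided bins 0..512
static const double FS = 1000.0;

// ---------------------------------------------------------------------------
// fixed-size radix-2 FFT machinery (length 1024 only)
// ---------------------------------------------------------------------------

static std::vector< std::complex<double> > g_tw;
static std::vector<int> g_bitrev;
static std::vector<double> g_hamming;
static double g_win_ssq = 0.0;

static void init_tables() {
  if (!g_tw.empty()) return;
  g_tw.resize(NFFT / 2);
  for (int i = 0; i < NFFT / 2; ++i)
    g_tw[i] = std::polar(1.0, -2.0 * M_PI * i / NFFT);
  g_bitrev.resize(NFFT);
  for (int i = 0; i < NFFT; ++i) {
    int r = 0, x = i;
    for (int b = 0; b < 10; ++b) { r = (r << 1) | (x & 1); x >>= 1; }
    g_bitrev[i] = r;
  }
  // symmetric Hamming window, the pwelch default taper
  g_hamming.resize(NFFT);
  g_win_ssq = 0.0;
  for (int i = 0; i < NFFT; ++i) {
    g_hamming[i] = 0.54 - 0.46 * std::cos(2.0 * M_PI * i / (NFFT - 1));
    g_win_ssq += g_hamming[i] * g_hamming[i];
  }
}

static void fft1024(std::complex<double>* a) {
  for (int i = 0; i < NFFT; ++i) {
    int j = g_bitrev[i];
    if (j > i) std::swap(a[i], a[j]);
  }
  for (int len = 2; len <= NFFT; len <<= 1) {
    int half = len >> 1, step = NFFT / len;
    for (int i = 0; i < NFFT; i += len) {
      for (int j = 0; j < half; ++j) {
        std::complex<double> u = a[i + j];
        std::complex<double> v = a[i + j + half] * g_tw[j * step];
        a[i + j] = u + v;
        a[i + j + half] = u - v;
      }
    }
  }
}

// Accumulate |FFT|^2 of two real segments (already tapered) through one
// complex transform; acc_a/acc_b get bins 0..512.
static void accum_periodogram_pair(const double* xa, const double* xb,
                                   double* acc_a, double* acc_b) {
  std::complex<double> buf[NFFT];
  for (int i = 0; i < NFFT; ++i) buf[i] = std::complex<double>(xa[i], xb[i]);
  fft1024(buf);
  for (int k = 0; k < NBIN; ++k) {
    std::complex<double> zk = buf[k];
    std::complex<double> zn = std::conj(buf[(NFFT - k) & (NFFT - 1)]);
    std::complex<double> A = 0.5 * (zk + zn);
    std::complex<double> B = std::complex<double>(0.0, -0.5) * (zk - zn);
    acc_a[k] += std::norm(A);
    acc_b[k] += std::norm(B);
  }
}

// One-sided density scaling: x2 except DC and Nyquist, / (fs * sum(w^2)).
static void finalize_psd(std::vector<double>& acc, int nseg, double* out) {
  double denom = FS * g_win_ssq * (double) nseg;
  for (int k = 0; k < NBIN; ++k) {
    double c = (k == 0 || k == NBIN - 1) ? 1.0 : 2.0;
    out[k] = c * acc[k] / denom;
  }
}

// Streaming Welch accumulator over prepared (demeaned) raw segments: applies
// the taper, packs segment pairs, accumulates periodograms.
struct WelchAccum {
  std::vector<double> acc;
  double pend[NFFT];
  bool have_pend;
  int nseg;
  WelchAccum() : acc(NBIN, 0.0), have_pend(false), nseg(0) {}
  void add(const double* seg, bool demean) {
    double buf[NFFT];
    double mu = 0.0;
    if (demean) {
      for (int i = 0; i < NFFT; ++i) mu += seg[i];
      mu /= NFFT;
    }
    for (int i = 0; i < NFFT; ++i) buf[i] = (seg[i] - mu) * g_hamming[i];
    if (!have_pend) {
      std::copy(buf, buf + NFFT, pend);
      have_pend = true;
    } else {
      accum_periodogram_pair(pend, buf, acc.data(), acc.data());
      have_pend = false;
    }
    ++nseg;
  }
  void finish(double* out) {
    if (have_pend) {
      double zero[NFFT] = {0.0};
      std::vector<double> acc2(2 * NBIN, 0.0);
      accum_periodogram_pair(pend, zero, acc2.data(), acc2.data() + NBIN);
      for (int k = 0; k < NBIN; ++k) acc[k] += acc2[k];
      have_pend = false;
    }
    finalize_psd(acc, nseg, out);
  }
};

// [[Rcpp::export]]
NumericVector cpp_welch_psd(NumericVector x, bool demean) {
  init_tables();
  int n = x.size();
  if (n <= 0 || n % NFFT != 0)
    stop("input length must be a positive multiple of 1024");
  int nseg = n / NFFT;
  WelchAccum w;
  for (int s = 0; s < nseg; ++s) w.add(&x[s * NFFT], demean);
  NumericVector out(NBIN);
  w.finish(REAL(out));
  return out;
}

// Segments supplied as a 1024 x nseg matrix, already demeaned/padded by the
// caller (windowed-data conventions); no further demeaning.
// [[Rcpp::export]]
NumericVector cpp_psd_from_segments(NumericMatrix segs) {
  init_tables();
  if (segs.nrow() != NFFT) stop("segments must have 1024 rows");
  int nseg = segs.ncol();
  if (nseg < 1) stop("need at least one segment");
  WelchAccum w;
  for (int s = 0; s < nseg; ++s) w.add(&segs(0, s), false);
  NumericVector out(NBIN);
  w.finish(REAL(out));
  return out;
}

// ---------------------------------------------------------------------------
// spike-train simulation
// ---------------------------------------------------------------------------

// Discrete-time inhomogeneous Poisson process with exponential recovery:
//   p_ss(t)  = p_base + p_osc * sin(2*pi*f_osc*t/1000)
//   p_spk(t) = p_ss(t)                    if latency n since last spike > n_r
//            = p_ss(t) * k^(n_r + 1 - n)  if n <= n_r
// p_base/p_osc are per-ms probabilities. Before the first spike the unit is
// treated as outside the recovery period. A spike at bin t sets n = 1 at t+1.
// [[Rcpp::export]]
IntegerVector cpp_simulate_train(int T, double p_base, double p_osc,
                                 double f_osc, int n_r, double k) {
  if (T <= 0) stop("T must be positive");
  if (n_r < 0) stop("n_r must be a non-negative integer");
  IntegerVector delta(T);
  // precompute k^(n_r + 1 - n) for n = 1..n_r
  std::vector<double> kpow(n_r + 1, 1.0);
  for (int n = 1; n <= n_r; ++n) kpow[n] = std::pow(k, (double)(n_r + 1 - n));
  double w = 2.0 * M_PI * f_osc * 0.001;
  long last = -1;  // bin index of last spike, -1 = none yet
  for (int t = 1; t <= T; ++t) {
    double p = p_base + p_osc * std::sin(w * t);
    if (last >= 0) {
      long n = t - last;
      if (n <= n_r) p *= kpow[n];
    }
    if (unif_rand() < p) {
      delta[t - 1] = 1;
      last = t;
    }
  }
  return delta;
}

// ---------------------------------------------------------------------------
// global ISI shuffling: mean surrogate PSD
// ---------------------------------------------------------------------------

// Mean Welch PSD (segment-demeaned) over n_surr ISI-shuffled surrogates of a
// train given by 1-based spike times. The first spike stays anchored at its
// original bin; permuted ISIs are appended after it.
// [[Rcpp::export]]
NumericVector cpp_shuffle_mean_psd(IntegerVector spike_times, int T,
                                   int n_surr) {
  init_tables();
  if (T <= 0 || T % NFFT != 0)
    stop("T must be a positive multiple of 1024");
  int nspk = spike_times.size();
  if (nspk < 2) stop("need at least 2 spikes to shuffle");
  if (n_surr < 1) stop("n_surrogates must be >= 1");
  int nisi = nspk - 1;
  std::vector<int> isi(nisi);
  for (int i = 0; i < nisi; ++i) {
    isi[i] = spike_times[i + 1] - spike_times[i];
    if (isi[i] <= 0) stop("spike times must be strictly increasing");
  }
  int t0 = spike_times[0];
  int nseg = T / NFFT;
  std::vector<double> mean_acc(NBIN, 0.0);
  std::vector<double> x(T);
  for (int s = 0; s < n_surr; ++s) {
    // Fisher-Yates permutation via R RNG
    for (int i = nisi - 1; i > 0; --i) {
      int j = (int) R_unif_index((double)(i + 1));
      std::swap(isi[i], isi[j]);
    }
    std::fill(x.begin(), x.end(), 0.0);
    long t = t0;
    x[t - 1] = 1.0;
    for (int i = 0; i < nisi; ++i) {
      t += isi[i];
      x[t - 1] = 1.0;
    }
    WelchAccum w;
    for (int g = 0; g < nseg; ++g) w.add(&x[g * NFFT], true);
    double out[NBIN];
    w.finish(out);
    for (int kk = 0; kk < NBIN; ++kk) mean_acc[kk] += out[kk];
  }
  NumericVector res(NBIN);
  for (int kk = 0; kk < NBIN; ++kk) res[kk] = mean_acc[kk] / n_surr;
  return res;
}
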