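# rpspect — recovery-period correction of spike-train power spectra

Single-unit spike trains carry a post-spike **recovery period** (RP): an
absolute refractory millisecond followed by a gradual return of spike
probability to its steady-state level. In the Welch power spectral density
(PSD) of a binary 1 kHz spike train this history effect distorts the
spectrum — low-frequency power is suppressed and ripples appear — which can
hide genuine oscillations (e.g. parkinsonian alpha/beta rhythms in basal
ganglia and motor thalamus single units) or fake spurious ones. The standard
fix, dividing by the mean PSD of ISI-shuffled surrogates, removes the
distortion *and* any oscillatory structure carried by the ISI distribution —
which, for sparse spike trains, is most of the signal.

`rpspect` implements and benchmarks a **residuals** correction that removes
only the bounded spike-history effect:

1. **RP duration estimation** — scan right-shifted exponential fits to the
   ISI density (Poisson GLM, log link): the deviance difference
   ΔD(L) = D₀ − D₁ peaks at the first lag where the cropped density turns
   exponential; the first interior local maximum gives n̂ᵣ = L − 1.
2. **Bounded last-spike point-process model** — a Poisson GLM
   log λ(t) = β₀ + Σⱼ βⱼ δ(t − j, s*(t)), j = 1..n̂ᵣ, where s*(t) is the
   most recent spike; fitted exactly via its grouped closed form (the
   concave-likelihood optimum IRLS converges to).
3. **Residual spectrum** — the Welch PSD of r(t) = I(t) − λ̂(t), with
   significance of points in (0,100] Hz judged against a one-sided CI built
   from the same spectrum's [250,500] Hz mean and SD, Bonferroni-split over
   the 102 searched bins.

The package also provides the Eq.-(1)-style simulator (inhomogeneous Poisson
with exponential recovery, sinusoidal rate modulation), the global
ISI-shuffling correction for unbroken and trial-windowed data, hit /
false-alarm labeling with subsampled partial-ROC comparison, and
Gaussian-mixture screening of task windows — everything needed to rerun the
synthetic benchmarking of the two corrections.

## Worked example

A sparse thalamus-like train: 11 Hz base rate, 60% modulated 9 Hz
oscillation, 9 ms recovery period (k = 0.7), one minute of data.

```r
library(rpspect)
p  <- sim_params(p_base = 11, f_osc = 9, m = 0.6, n_r = 9, k = 0.7,
                 T = 60 * 1024)
tr <- simulate_spike_train(p, seed = 7)
tr
#> spike_train: T=61440 ms, 622 spikes (10.12 Hz)

est <- estimate_rp_duration(tr)
est
#> rp_estimate: n_r_hat = 8 ms (searched L = 1..10)

res <- residuals_corrected_psd(tr, n_r_hat = est$n_r_hat)
significance_test(res$psd, alpha_c = 0.05)
#> significance_result: alpha_c=0.05, threshold=2.903e-05, 1/102 bins significant
#>   at: 8.7891 Hz

shuf <- shuffling_corrected_psd(tr, n_surrogates = 100)
significance_test(shuf$corrected, alpha_c = 0.05)
#> significance_result: alpha_c=0.05, threshold=1.39, 1/102 bins significant
#>   at: 8.7891 Hz
```

The estimated recovery period (8 ms, one off the 9 ms ground truth — within
the estimator's typical ±1 ms scatter at this sparseness) bounds the
point-process model; the residual spectrum flags exactly one significant
point, at 8.79 Hz, the grid bin nearest the implanted 9 Hz oscillation. At
this moderate sparseness both corrections succeed; as rates drop toward (or
below) the oscillation frequency, shuffling increasingly absorbs the peak
into its control spectrum while the residuals method keeps detecting it —
that sensitivity gap, and the methods' false-alarm behavior, is what the
evaluation grid quantifies.

A shell entry point covers the same workflows
(`simulate`, `correct`, `rp-estimate`, `evaluate`, `roc`,
`screen-windows`):

```sh
Rscript exec/rpspect correct residuals --input train.csv --out psd.csv
```

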