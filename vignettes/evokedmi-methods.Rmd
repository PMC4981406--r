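---
title: "Estimating tone-frequency information in evoked-potential features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tone-frequency information in evoked-potential features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evokedmi)
```

## The problem

In tone-mapping experiments on primary auditory cortex, an anesthetized
animal hears tones of `M = 32` frequencies (logarithmically spaced from
2 kHz to 46,731 Hz, 25 ms long, pseudo-random order) while two signals are
recorded simultaneously at 4000 samples/s: the postsynaptic potential (PSP)
of one patched neuron and a nearby local field potential (LFP).  Each trial
is reduced to two continuous features of the filtered, baseline-corrected
sweep — the amplitude (window maximum minus minimum) and the latency (onset
to extremum) — and the scientific question is how much information those
features carry about the tone frequency.  That quantity is the mutual
information (MI) between a *discrete* stimulus $S$ and a *continuous*
response $R$:

$$I(S;R)=\sum_s \int \mu(s,r)\,\log_2\frac{\mu(s,r)}{p(s)\,\mu_R(r)}\,dr .$$

Estimating this from a few hundred trials per cell is the hard part, and
most of this package is machinery for doing that estimation credibly:
estimators, analytic ground truth to calibrate them against, a synthetic
experiment generator with known information content, and the nonparametric
group comparisons used to contrast signals, features and treatment groups.

## Estimators

**Nearest-neighbour estimator** (`mi_knn()`).  For each point $i$, let
$N_{S_i}$ be the number of points sharing its label, $d_i$ the distance to
its $k$-th nearest same-label neighbour on the response axis, and $m_i$ the
number of points of *any* label within $d_i$ (closed ball, $i$ excluded).
Then

$$I_i=\psi(N)-\psi(N_{S_i})+\psi(k)-\psi(m_i),\qquad
\hat I=\frac{1}{N}\sum_i I_i$$

in nats, reported in bits.  Design choices worth knowing:

* $m_i$ counts over **all** points.  The verbal description of this
  estimator is sometimes garbled into counting within the same label; the
  all-label convention is the one that makes a single-label dataset come
  out at exactly zero (then $m_i = k$ and $\psi(N)-\psi(N)=0$), and it is
  what the test suite pins down against a brute-force $O(N^2)$ oracle.
* Ties are counted with $\le d_i$; exact response ties inflate $m_i$, so
  the estimator is meant for genuinely continuous features (the test
  fixtures are tie-free).
* A label seen only once has no same-label neighbour: such points are
  skipped, counted in `skipped_points`, and warned about.  If $k$ exceeds
  $N_{S_i}-1$ the per-point order is reduced to $k_i=\min(k, N_{S_i}-1)$,
  which keeps unbalanced designs estimable instead of failing globally.
* The estimate is exactly invariant under affine response maps and can be
  slightly negative on weakly informative data; `clamp_mi()` floors it at
  zero, applied per cell *before* any averaging across cells.  The default
  `k = 3` follows the common recommendation for this estimator family.

**Binned plug-in and quadratic extrapolation** (`mi_binned()`, `mi_qe()`).
The classical alternative bins the response into `n_bins` equal-width bins
over the observed range (the simplest reading of "binning"; the maximum
closes the last bin) and plugs relative frequencies into the discrete MI
formula.  This is positively biased at finite $N$, approximately
$a/N+b/N^2$; `mi_qe()` estimates the bias by computing the naive estimator
on the full set, on 2 random halves (averaged) and on 4 random quarters
(averaged), then solving the exactly determined system for
$(I_{true},a,b)$ — `qe_fit()` exposes the solve so stubbed bias curves can
be inverted exactly in tests.  One seeded random partition per level is
used; the partition seed is an explicit argument.

## Analytic ground truth and the calibration experiments

`mixture_spec()` describes a labelled mixture (discrete prior + per-class
Gaussian or uniform conditional) whose MI is computable: all-uniform specs
in closed form (the integrand is piecewise constant between support
endpoints), anything with a Gaussian by adaptive quadrature of each
component's KL term over mean $\pm 9$ sd (absolute tolerance well below
$10^{-6}$ bits; uniform support edges are used as split points so the
integrand is smooth on every piece).

Two canonical two-class calibration models ship with the package:

* `uniform_pair_spec(width = 4)` — equiprobable uniforms centered at 1 and
  2 with total width 4; MI is exactly $1-\tfrac34 = 0.25$ bit.  The
  narrower literal reading of "a rectangular pulse of width 2" gives
  exactly 0.5 bit and is available as `uniform_pair_spec(width = 2)`;
  the two are easy to confuse when the pulse is rescaled, which is why
  both are shipped and documented.
* `gaussian_pair_spec()` — equiprobable unit-variance Gaussians at means
  1 and 2; quadrature gives 0.1607 bits.  A reference value of 0.08 bit is
  sometimes quoted for this pair; direct integration shows that value is
  half the actual integral (the same factor-2 pattern as the
  0.25-versus-0.5 uniform case), so the package reports what the integral
  gives and leaves the discrepancy visible rather than adopting a rescaled
  model that happens to round to the quoted number.

`run_calibration()` replicates the standard validation figure: 100
datasets of $N=400$, the estimate summarised (mean, 10%–90% band) across a
parameter sweep — `k` from 1–10 for the neighbour estimator, bin counts
1–400 for binned-QE.  On the Gaussian pair the neighbour estimator's mean
at `k = 3` lands within ±0.02 bit of truth, its variation across the whole
`k` grid is far smaller than the binned estimator's variation across bin
counts, and the uncorrected plug-in overshoots truth once bins are fine
(≥ 100 bins at $N=400$) — the three qualitative facts that motivate using
the neighbour estimator on real features.  The acceptance suite runs the
bin grid thinned to every 5th value, which does not change any of those
verdicts.  Replicate $i$ uses seed `base_seed + i`, making every summary
reproducible bit-for-bit.

## Signal front-end

Sweeps live in a tibble (one row per trial, trace in a list-column) and
flow through three chained steps:

* `lowpass_filter()` — linear-phase least-squares FIR low-pass, order 39,
  passband edge 300 Hz, transition band 15% of the cutoff (the documented
  default of the standard EEG filtering routine this reconstructs), applied
  forward and backward so the net phase is zero and the net gain is
  $|H(f)|^2$.  The design is a dense-grid linear least-squares fit of the
  symmetric amplitude response, with taps normalised so DC gain is exactly
  1.  Edges are reflect-padded by 3 filter orders; the implementation
  convolves with the filter's autocorrelation via FFT, which equals
  explicit two-pass filtering to machine precision (asserted in tests) but
  runs in $O(n\log n)$ per sweep.  The contract is expressed through
  measurable gain properties (DC within $10^{-3}$, sinusoid gains matching
  the designed $|H|^2$) rather than specific coefficients.
* `baseline_correct()` — subtracts the mean over $[0,\,\mathrm{onset})$
  (the first 15 ms by default), so every trace is potential relative to its
  pre-stimulus baseline.
* `extract_features()` — over the half-open analysis window
  $[15, 100)$ ms: amplitude = max − min (so it is nonnegative for both
  polarities), latency = onset to the window maximum (PSP) or minimum
  (LFP), ties broken by the earliest sample.  Latencies are therefore in
  $[0, 85]$ ms.  Features are taken from the *filtered* trace.  Flat
  windows yield amplitude 0 with a `degenerate` flag instead of an error,
  so a dead sweep cannot kill a batch run.

Internally everything is 0-based samples and seconds; milliseconds appear
only at reporting boundaries.  Sweep sets are stored as one plain CSV per
cell (`write_sweep_store()`); a reader for the original study's raw files
is deliberately a documented stub (`read_crcns_sweeps()`) because that
archive is registration-gated and its layout unpublished.

## The synthetic experiment generator

`generate_sweeps()` emulates the *structure* of the real experiment — 32
log-spaced tones presented in balanced pseudo-random blocks, paired
simultaneous PSP/LFP sweeps, 4 kHz sampling, onset at 15 ms — with a
mechanistic but deliberately simple response model: an alpha-shaped evoked
deflection $a\,u e^{1-u}$, $u=(t-t_0)/\tau$, $\tau = 10$ ms, whose peak
amplitude follows a Gaussian tuning curve in log-frequency plus Gaussian
trial noise, with jittered latency, white background noise, and an
LFP polarity/gain transform.  Defaults (5 mV peak tuning, 0.5 mV amplitude
noise, 0.1 mV background noise, 25 ms latency with 2 ms jitter, 50 trials
per frequency) were chosen once to match the few-mV deflection scale of
published example sweeps; they are the package's standing study
conditions, not tuning knobs.

Because amplitude noise is Gaussian around the tuning curve, the true MI
of the amplitude feature is the MI of a 32-component Gaussian mixture —
`model_true_mi()` computes it with the same quadrature machinery, using
the unscaled tuning curve since gain and polarity are affine maps that
cannot change MI.  This gives an end-to-end target: run the full pipeline
(generate → filter → baseline → features → `mi_knn`) and compare with the
model's ground truth.  At 100 trials per tone, averaged over 20 seeds, the
pipeline recovers each cell's true amplitude MI within ±0.05 bit; and a
population whose LFP models have lower relative amplitude noise than their
paired PSPs (`random_population(lfp_noise_factor = 0.5)`) reproduces, in
at least 90% of seeds at 33 cells, the qualitative ordering that the LFP
amplitude is the more informative signal (paired one-tailed signed rank,
p < 0.05).  The dominance check runs at 25 trials per tone — the ordering
is a between-signal contrast and does not need the trial count that
per-cell recovery does.

What the generator does *not* model, and what passing these tests
therefore does not establish about real recordings: correlated or
non-Gaussian noise, across-trial adaptation or anesthesia depth drift,
spikes riding on the PSP, non-Gaussian tuning shapes, or any dependence of
latency structure on frequency beyond the shared mean.  The generator
validates the estimation machinery, not cortical physiology.

## Group comparisons

`estimate_mi_features()` produces the per-cell MI table (cell × signal ×
feature, clamped), `mi_summary()` the mean ± SEM rows, and two
nonparametric tests the contrasts: `paired_signed_rank()` for matched
per-cell comparisons (amplitude vs latency within a signal, PSP vs LFP
within a feature) and `unpaired_rank_sum()` for independent groups (e.g.
anesthetic).  Both drop zero differences with a report, use average ranks,
and switch between an exact null distribution — built by integer
polynomial convolution over doubled ranks, equivalent to full enumeration
— and the tie-corrected, continuity-corrected normal approximation.  The
thresholds (exact up to $n=15$ pairs, $m+n=12$) were set so that
study-scale comparisons (33 pairs; 16 vs 17 cells) use the approximation,
as any standard implementation would, while the exact mode remains small
enough to verify against brute-force enumeration.  Tail directions are
configuration, not hard-coded: the conventional contrast set
(`default_contrasts()`) marks the hypothesised one-tailed directions
explicitly.  No multiple-testing correction is applied, matching common
practice for these few planned contrasts; `p.adjust()` can be applied to
the returned column by users who want it.

## End-to-end runs and reproducibility

`run_pipeline(pipeline_config(...))` composes the whole analysis and
returns features, the clamped MI table, summaries and contrast results,
stamped with a config hash, the seed and the package version; outputs
written via `write_mi_table()` carry that provenance as a `#` header.
Every random step (mixture sampling, QE partitions, sweep generation,
calibration replicates) is seeded from explicit arguments, so identical
configs give bit-identical tables.  Estimator failures on single cells are
warned about and excluded rather than fatal.

Problem sizes used by the test suite — 100 × N=400 calibration replicates,
a 5-step bin grid to 400, 3 cells × 20 seeds at 100 trials/tone for
recovery, 33 cells × 20 seeds at 25 trials/tone for the dominance check —
are the package's chosen standing conditions for those experiments.

## Known limitations

* The neighbour estimator's tie handling (closed ball) biases $m_i$ upward
  on discretised responses; don't feed it heavily rounded features.
* Equal-width binning over the observed range makes `mi_binned()`
  sensitive to outliers through the range; that sensitivity is part of
  what the calibration experiment demonstrates.
* `true_mi()` quadrature assumes one-dimensional responses and
  Gaussian/uniform conditionals; multivariate features are out of scope.
* The QE correction uses a single random partition per level; its own
  replicate-to-replicate spread is visible in the calibration bands.
* Latency MI on synthetic data is near zero by construction (latency
  jitter is frequency-independent), so synthetic experiments exercise the
  latency *pathway*, not latency coding.
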