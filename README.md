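# evokedmi

Tools for asking how much information the features of tone-evoked neural
potentials carry about the tone.  In tone-mapping experiments a rat hears
32 log-spaced tone frequencies (2 kHz–46,731 Hz, 25 ms, pseudo-random
order) while a patched neuron's postsynaptic potential (PSP) and a nearby
local field potential (LFP) are recorded at 4 kHz.  Each sweep is reduced
to an amplitude (window max − min) and a latency (onset to extremum), and
the question "how well does this feature encode frequency?" is answered
with the mutual information between the discrete stimulus $S$ and the
continuous feature $R$:

$$I(S;R)=\sum_s \int \mu(s,r)\,\log_2\frac{\mu(s,r)}{p(s)\,\mu_R(r)}\,dr$$

The package provides, as a pipeable tidyverse-style toolkit:

* **Estimators** for discrete–continuous MI: the nearest-neighbour
  (digamma) estimator `mi_knn()` with per-point diagnostics and clamping
  (`clamp_mi()`), the binned plug-in estimator `mi_binned()`, and its
  quadratic-extrapolation bias correction `mi_qe()` / `qe_fit()`.
* **Analytic ground truth** for labelled Gaussian/uniform mixtures
  (`mixture_spec()`, `true_mi()`, `sample_mixture()`) and calibration
  experiments sweeping `k` or the bin count over replicate datasets
  (`run_calibration()`, with `autoplot()`).
* **Signal front-end**: zero-phase least-squares FIR low-pass
  (`design_lowpass_fir()`, `lowpass_filter()`), baseline correction and
  amplitude/latency extraction (`baseline_correct()`,
  `extract_features()`), plus a plain-text sweep store.
* **Synthetic experiments** with the study's structure and *known*
  information content (`experiment_spec()`, `generate_sweeps()`,
  `model_true_mi()`, `random_population()`), so the whole chain is
  testable without any data download.
* **Group statistics**: per-cell MI tables (`estimate_mi_features()`),
  mean ± SEM summaries (`mi_summary()`), exact/approximate Wilcoxon
  signed-rank and rank-sum comparisons (`paired_signed_rank()`,
  `unpaired_rank_sum()`), and an end-to-end runner (`run_pipeline()`).

See `vignettes/evokedmi-methods.Rmd` for the model, the estimator
conventions, and the design decisions.

## Worked example

Estimate MI on data drawn from a model whose true MI is known:

```r
library(evokedmi)

d <- sample_mixture(gaussian_pair_spec(), n = 400, seed = 42)
mi_knn(d, k = 3)
#> <mi_estimate> knn (k = 3), n = 400
#>   I = 0.1500 bits
true_mi(gaussian_pair_spec())
#> [1] 0.1607472
```

The estimate (0.150 bits from 400 samples) sits close to the analytic
value of the generating mixture (0.1607 bits).  A full synthetic
experiment — 4 cells, paired PSP/LFP sweeps, 25 presentations of each of
32 tones — runs end to end in a few seconds:

```r
cfg <- pipeline_config(
  experiment = experiment_spec(cells = random_population(4, seed = 8),
                               trials_per_freq = 25, seed = 99)
)
res <- run_pipeline(cfg)
res$summary
#> # A tibble: 4 × 7
#>   signal_type feature   group   mean    sem     n sem_defined
#>   <chr>       <chr>     <chr>  <dbl>  <dbl> <int> <lgl>
#> 1 LFP         amplitude all   2.26   0.0759     4 TRUE
#> 2 LFP         latency   all   0.0120 0.0120     4 TRUE
#> 3 PSP         amplitude all   1.53   0.0670     4 TRUE
#> 4 PSP         latency   all   0.0109 0.0109     4 TRUE
res$contrasts[, c("name", "n_used", "statistic", "p_value")]
#> # A tibble: 4 × 4
#>   name               n_used statistic p_value
#> 1 psp_amp_vs_psp_lat      4        10  0.0625
#> 2 lfp_amp_vs_lfp_lat      4        10  0.0625
#> 3 lfp_amp_vs_psp_amp      4        10  0.0625
#> 4 psp_lat_vs_lfp_lat      1         0  1
```

Amplitudes carry ~1.5 bits (PSP) and ~2.3 bits (LFP) about the tone in
this population — the default `random_population()` gives LFPs lower
relative amplitude noise, so the LFP amplitude dominates by construction —
while latencies carry essentially none (latency jitter is
frequency-independent in the generator).  With only 4 cells the exact
one-tailed signed-rank floor is 1/16 = 0.0625; at study scale (33 cells)
the same ordering is significant in ≥ 90% of seeds (see the acceptance
tests).  The per-cell ground truths are available for comparison:

```r
sapply(cfg$experiment$cells, function(cl) model_true_mi(cl$psp))
#>   c01   c02   c03   c04
#> 1.474 1.594 1.352 1.443
```

(Pipeline estimates at 25 trials/tone sit slightly above these truths from
residual small-sample bias; the recovery test runs at 100 trials/tone,
where per-cell estimates land within ±0.05 bit.)

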