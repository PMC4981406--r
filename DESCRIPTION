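Package: evokedmi
Title: Mutual Information Between Tone Stimuli and Evoked-Potential Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates mutual information between a discrete tone-frequency
    stimulus and continuous features (amplitude, latency) of evoked
    postsynaptic potentials (PSP) and local field potentials (LFP).
    Implements the Ross k-nearest-neighbour estimator for discrete-continuous
    pairs, the binned plug-in estimator with quadratic-extrapolation bias
    correction, analytic ground-truth mutual information for labelled mixture
    models, estimator calibration experiments, zero-phase FIR filtering and
    amplitude/latency feature extraction for trial-aligned sweeps, a
    synthetic tone-experiment generator with known information content, and
    nonparametric paired and unpaired group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
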