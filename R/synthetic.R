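#' Frequency-tuning model for one recorded signal
#'
#' Describes how a simulated cell's evoked response depends on tone
#' frequency: a Gaussian tuning curve in log-frequency (octaves) for the
#' evoked amplitude, trial-to-trial amplitude noise, a mean response latency
#' with jitter, background trace noise, and the polarity/gain of the signal
#' (+1 for an upward PSP deflection, -1 for a downward LFP deflection; LFPs
#' summing many neurons get `gain > 1`).
#'
#' @param preferred_freq_hz tuning-curve peak frequency (Hz).
#' @param tuning_width_octaves tuning-curve standard deviation in octaves.
#' @param max_amplitude_mv evoked amplitude at the preferred frequency (mV).
#' @param amplitude_noise_sd_mv trial-to-trial amplitude noise sd (mV).
#' @param latency_base_ms mean time from stimulus onset to the response
#'   extremum (ms).
#' @param latency_jitter_sd_ms latency jitter sd (ms).
#' @param background_noise_sd_mv additive white trace noise sd (mV).
#' @param polarity +1 (PSP) or -1 (LFP).
#' @param gain amplitude multiplier (LFP population gain).
#' @return An object of class `tuning_model`.
#' @export
tuning_model <- function(preferred_freq_hz = 8000,
                         tuning_width_octaves = 1.5,
                         max_amplitude_mv = 5,
                         amplitude_noise_sd_mv = 0.5,
                         latency_base_ms = 25,
                         latency_jitter_sd_ms = 2,
                         background_noise_sd_mv = 0.1,
                         polarity = 1,
                         gain = 1) {
  if (tuning_width_octaves <= 0 || gain <= 0 ||
      amplitude_noise_sd_mv < 0 || latency_jitter_sd_ms < 0 ||
      background_noise_sd_mv < 0) {
    abort("tuning widths, noise sds and gain must be valid (> 0 / >= 0)")
  }
  if (!polarity %in% c(-1, 1)) abort("polarity must be +1 (PSP) or -1 (LFP)")
  structure(
    list(
      preferred_freq_hz = preferred_freq_hz,
      tuning_width_octaves = tuning_width_octaves,
      max_amplitude_mv = max_amplitude_mv,
      amplitude_noise_sd_mv = amplitude_noise_sd_mv,
      latency_base_ms = latency_base_ms,
      latency_jitter_sd_ms = latency_jitter_sd_ms,
      background_noise_sd_mv = background_noise_sd_mv,
      polarity = polarity,
      gain = gain
    ),
    class = "tuning_model"
  )
}

#' Evaluate a tuning curve
#'
#' Mean evoked amplitude (before gain) at the given tone frequencies:
#' `max_amplitude_mv * exp(-oct^2 / (2 * width^2))` with `oct` the distance
#' from the preferred frequency in octaves.
#'
#' @param model a [tuning_model()].
#' @param freq_hz tone frequencies (Hz).
#' @return Mean amplitudes (mV).
#' @export
tuning_amplitude <- function(model, freq_hz) {
  oct <- log2(freq_hz / model$preferred_freq_hz)
  model$max_amplitude_mv * exp(-oct^2 / (2 * model$tuning_width_octaves^2))
}

#' Specification of a synthetic tone experiment
#'
#' Defines the stimulus protocol and recorded population of a surrogate
#' experiment: 32 tone frequencies logarithmically spaced between 2 kHz and
#' 46,731 Hz, 25 ms tones presented in pseudo-random order, and one pair of
#' simultaneously recorded signals (PSP and LFP) per cell, sampled at
#' 4000 Hz with stimulus onset 15 ms into each 110 ms sweep.
#'
#' @param cells named or unnamed list; each element is a
#'   `list(psp = tuning_model(...), lfp = tuning_model(...))`.
#' @param trials_per_freq presentations of each frequency per cell
#'   (default 50).
#' @param n_freqs,freq_lo_hz,freq_hi_hz frequency-grid geometry.
#' @param tone_dur_ms tone duration (ms, protocol metadata).
#' @param sampling_rate sampling rate (Hz).
#' @param onset_s stimulus onset within each sweep (s).
#' @param sweep_dur_s sweep length (s, `>= 0.110`).
#' @param alpha_tau_s rise time constant of the alpha-shaped evoked
#'   deflection (s); the deflection peaks `alpha_tau_s` after its foot.
#' @param seed integer seed driving all randomness in the experiment.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(cells = list(),
                            trials_per_freq = 50,
                            n_freqs = 32,
                            freq_lo_hz = 2000,
                            freq_hi_hz = 46731,
                            tone_dur_ms = 25,
                            sampling_rate = 4000,
                            onset_s = 0.015,
                            sweep_dur_s = 0.110,
                            alpha_tau_s = 0.010,
                            seed = 1) {
  if (trials_per_freq < 1) abort("trials_per_freq must be >= 1")
  if (n_freqs < 2 || freq_lo_hz <= 0 || freq_hi_hz <= freq_lo_hz) {
    abort("invalid frequency grid")
  }
  if (sweep_dur_s < onset_s + 0.085) abort("sweep too short for the analysis window")
  structure(
    list(
      cells = cells,
      trials_per_freq = as.integer(trials_per_freq),
      n_freqs = as.integer(n_freqs),
      freq_lo_hz = freq_lo_hz,
      freq_hi_hz = freq_hi_hz,
      tone_dur_ms = tone_dur_ms,
      sampling_rate = sampling_rate,
      onset_s = onset_s,
      sweep_dur_s = sweep_dur_s,
      alpha_tau_s = alpha_tau_s,
      seed = as.integer(seed)
    ),
    class = "experiment_spec"
  )
}

#' The logarithmic tone-frequency grid
#'
#' Geometric progression `f_i = lo * (hi/lo)^(i/(n-1))`, `i = 0..n-1`;
#' endpoints are exact.
#'
#' @param spec an [experiment_spec()].
#' @return Numeric vector of `n_freqs` frequencies (Hz).
#' @export
#' @examples
#' make_frequency_grid(experiment_spec())[c(1, 32)] # 2000, 46731
make_frequency_grid <- function(spec = experiment_spec()) {
  i <- seq_len(spec$n_freqs) - 1
  f <- spec$freq_lo_hz * (spec$freq_hi_hz / spec$freq_lo_hz)^(i / (spec$n_freqs - 1))
  f[1] <- spec$freq_lo_hz
  f[spec$n_freqs] <- spec$freq_hi_hz
  f
}

#' Generate the sweeps of a synthetic experiment
#'
#' For every cell, tones are presented in balanced pseudo-random order (a
#' fresh permutation of the full frequency grid per block of `n_freqs`
#' trials, `trials_per_freq` blocks).  Each trial produces one PSP and one
#' LFP sweep sharing the stimulus: white background noise plus an
#' alpha-shaped evoked deflection `a * u * exp(1 - u)`,
#' `u = (t - t0)/tau`, whose peak amplitude `a` is drawn from the signal's
#' tuning model (`gain * (tuning + Gaussian amplitude noise)`, polarity
#' applied to the waveform) and whose peak time is the model latency plus
#' jitter.  Fully reproducible from `spec$seed`.
#'
#' @param spec an [experiment_spec()] with at least one cell.
#' @return A sweep table (see [check_sweeps()]) with
#'   `2 * n_freqs * trials_per_freq` rows per cell.
#' @export
generate_sweeps <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (length(spec$cells) == 0) abort("experiment_spec has no cells")
  freqs <- make_frequency_grid(spec)
  fs <- spec$sampling_rate
  n_time <- round(spec$sweep_dur_s * fs)
  t <- (seq_len(n_time) - 1) / fs
  cell_ids <- names(spec$cells)
  if (is.null(cell_ids)) cell_ids <- sprintf("c%02d", seq_along(spec$cells))
  withr::with_seed(spec$seed, {
    purrr::map_dfr(seq_along(spec$cells), function(ci) {
      models <- spec$cells[[ci]]
      if (!all(c("psp", "lfp") %in% names(models))) {
        abort("each cell must provide 'psp' and 'lfp' tuning models")
      }
      order_f <- as.vector(vapply(
        seq_len(spec$trials_per_freq),
        function(b) sample.int(spec$n_freqs),
        integer(spec$n_freqs)
      ))
      stim <- freqs[order_f]
      n_tr <- length(stim)
      purrr::map_dfr(c("PSP", "LFP"), function(sig) {
        m <- models[[tolower(sig)]]
        a <- m$gain * (tuning_amplitude(m, stim) +
                         rnorm(n_tr, 0, m$amplitude_noise_sd_mv))
        peak_s <- spec$onset_s +
          (m$latency_base_ms + rnorm(n_tr, 0, m$latency_jitter_sd_ms)) / 1000
        t0 <- peak_s - spec$alpha_tau_s
        u <- pmax(outer(t, t0, "-") / spec$alpha_tau_s, 0)
        shape <- u * exp(1 - u) # 0 at the foot, peak 1 at u = 1
        vals <- m$polarity * shape * rep(a, each = n_time) +
          matrix(rnorm(n_time * n_tr, 0, m$background_noise_sd_mv), n_time)
        tibble(
          cell_id = cell_ids[ci],
          trial_id = seq_len(n_tr),
          signal_type = sig,
          stimulus_freq_hz = stim,
          sampling_rate = fs,
          onset_s = spec$onset_s,
          values = asplit(vals, 2)
        )
      })
    })
  })
}

#' Ground-truth information content of a tuning model
#'
#' The amplitude feature of a noiseless pipeline is Gaussian around the
#' tuning curve, so the true MI between the uniformly presented
#' `n_freqs`-valued stimulus and the amplitude is the MI of a Gaussian
#' mixture with means at the tuning-curve values and common sd
#' `amplitude_noise_sd_mv`, computed by quadrature via [true_mi()].  Gain
#' and polarity are affine maps of the feature and cannot change MI, so the
#' unscaled curve is used.
#'
#' @param model a [tuning_model()] with `amplitude_noise_sd_mv > 0`.
#' @param spec an [experiment_spec()] supplying the frequency grid.
#' @return True MI in bits.
#' @export
model_true_mi <- function(model, spec = experiment_spec()) {
  if (model$amplitude_noise_sd_mv <= 0) {
    abort("amplitude noise sd must be > 0 (zero noise makes MI degenerate)")
  }
  means <- tuning_amplitude(model, make_frequency_grid(spec))
  true_mi(mixture_spec("gaussian", location = means,
                       scale = model$amplitude_noise_sd_mv))
}

#' Build a plausible recorded population
#'
#' Draws `n_cells` paired PSP/LFP tuning models: preferred frequencies
#' log-uniform over the stimulus range, tuning widths 1-2 octaves, peak
#' amplitudes 3-6 mV.  The LFP model of each cell shares the cell's tuning
#' but has inverted polarity, population gain `lfp_gain`, and amplitude
#' noise scaled by `lfp_noise_factor`; values below 1 make the LFP the more
#' informative signal of every pair, which is how an LFP-dominant population
#' is constructed for qualitative comparisons.
#'
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @param lfp_gain LFP amplitude multiplier (default 2).
#' @param lfp_noise_factor LFP amplitude-noise sd relative to the PSP's
#'   (default 0.5, i.e. LFP-dominant).
#' @param spec an [experiment_spec()] supplying the frequency range.
#' @return A named list of `list(psp = , lfp = )` pairs, ready for
#'   [experiment_spec()].
#' @export
random_population <- function(n_cells, seed, lfp_gain = 2,
                              lfp_noise_factor = 0.5,
                              spec = experiment_spec()) {
  withr::with_seed(seed, {
    pop <- lapply(seq_len(n_cells), function(i) {
      pref <- exp(runif(1, log(spec$freq_lo_hz * 1.5), log(spec$freq_hi_hz / 1.5)))
      width <- runif(1, 1, 2)
      amp <- runif(1, 3, 6)
      noise <- runif(1, 0.4, 0.6)
      lat <- runif(1, 20, 30)
      psp <- tuning_model(
        preferred_freq_hz = pref, tuning_width_octaves = width,
        max_amplitude_mv = amp, amplitude_noise_sd_mv = noise,
        latency_base_ms = lat, polarity = 1, gain = 1
      )
      lfp <- tuning_model(
        preferred_freq_hz = pref, tuning_width_octaves = width,
        max_amplitude_mv = amp,
        amplitude_noise_sd_mv = noise * lfp_noise_factor,
        latency_base_ms = lat + 2, polarity = -1, gain = lfp_gain
      )
      list(psp = psp, lfp = lfp)
    })
    names(pop) <- sprintf("c%02d", seq_len(n_cells))
    pop
  })
}
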