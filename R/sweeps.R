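#' Trial-aligned sweep tables
#'
#' A sweep set is a tibble with one row per trial and columns `cell_id`,
#' `trial_id`, `signal_type` (`"PSP"` or `"LFP"`), `stimulus_freq_hz`,
#' `sampling_rate` (Hz), `onset_s` (stimulus onset within the sweep, s) and
#' `values` (list-column of numeric voltage traces in mV).  All sweep
#' operations take and return this shape, so they chain with the pipe.
#'
#' @param data candidate sweep table.
#' @return `data`, invisibly, after validation.
#' @keywords internal
check_sweeps <- function(data) {
  needed <- c("cell_id", "trial_id", "signal_type", "stimulus_freq_hz",
              "sampling_rate", "onset_s", "values")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste("sweep table is missing columns:", paste(missing, collapse = ", ")))
  }
  if (!is.list(data$values)) abort("'values' must be a list-column of numeric traces")
  if (!all(data$signal_type %in% c("PSP", "LFP"))) {
    abort("signal_type must be 'PSP' or 'LFP'")
  }
  invisible(data)
}

# group rows by (sampling_rate, trace length) and apply f to the
# samples-by-trials matrix of each group; returns the modified sweep table
map_sweep_matrix <- function(data, f) {
  len <- lengths(data$values)
  grp <- paste(data$sampling_rate, len, data$onset_s)
  out <- data$values
  for (g in unique(grp)) {
    idx <- which(grp == g)
    m <- matrix(unlist(data$values[idx], use.names = FALSE),
                nrow = len[idx[1]], ncol = length(idx))
    m <- f(m, fs = data$sampling_rate[idx[1]], onset_s = data$onset_s[idx[1]])
    dim(m) <- NULL
    out[idx] <- split(m, rep(seq_along(idx), each = len[idx[1]]))
  }
  data$values <- out
  data
}

#' Design a linear-phase least-squares FIR low-pass filter
#'
#' Minimises the integrated squared error between the filter's amplitude
#' response and an ideal low-pass over a dense frequency grid, with
#' passband `[0, cutoff]` (desired gain 1) and stopband
#' `[cutoff * (1 + transition), Nyquist]` (desired gain 0); the transition
#' band is left unconstrained.  The impulse response is linear phase
#' (symmetric) with `order + 1` taps.
#'
#' @param cutoff_hz passband edge (Hz); must be below Nyquist.
#' @param sampling_rate sampling rate (Hz).
#' @param order filter order (default 39, i.e. 40 taps).
#' @param transition transition-band width as a fraction of the cutoff
#'   (default 0.15).
#' @return Numeric vector of `order + 1` filter coefficients.
#' @export
#' @examples
#' h <- design_lowpass_fir(300, 4000)
#' fir_gain(h, 0, 4000)    # ~1 at DC
#' fir_gain(h, 1000, 4000) # deep in the stopband
design_lowpass_fir <- function(cutoff_hz, sampling_rate, order = 39,
                               transition = 0.15) {
  nyq <- sampling_rate / 2
  if (cutoff_hz >= nyq) abort("cutoff must be below the Nyquist frequency")
  stop_lo <- min(cutoff_hz * (1 + transition), nyq)
  n_taps <- order + 1L
  # amplitude response basis: even taps -> Type II, A(w) = sum c_n cos(w(n - 1/2))
  # odd taps -> Type I,  A(w) = c_0 + sum c_n cos(w n)
  grid_band <- function(lo, hi, n) lo + (hi - lo) * (0:(n - 1)) / (n - 1)
  w_pass <- pi * grid_band(0, cutoff_hz, 512L) / nyq
  w_stop <- pi * grid_band(stop_lo, nyq, 512L) / nyq
  w <- c(w_pass, w_stop)
  d <- c(rep(1, length(w_pass)), rep(0, length(w_stop)))
  h <- if (n_taps %% 2 == 0) {
    m <- n_taps / 2
    basis <- outer(w, seq_len(m) - 0.5, function(wi, ni) cos(wi * ni))
    cfs <- qr.solve(basis, d)
    half <- cfs / 2
    c(rev(half), half)
  } else {
    m <- (n_taps - 1) / 2
    basis <- cbind(1, outer(w, seq_len(m), function(wi, ni) cos(wi * ni)))
    cfs <- qr.solve(basis, d)
    c(rev(cfs[-1] / 2), cfs[1], cfs[-1] / 2)
  }
  h / sum(h) # pin the DC gain at exactly 1
}

#' Magnitude response of an FIR filter
#'
#' Evaluates `|H(f)|` for a single pass of the filter; the two-way
#' (forward-backward) application used by [lowpass_filter()] has gain
#' `|H(f)|^2`.
#'
#' @param h FIR coefficients.
#' @param freq_hz frequencies at which to evaluate (Hz).
#' @param sampling_rate sampling rate (Hz).
#' @return Numeric vector of single-pass magnitude gains.
#' @export
fir_gain <- function(h, freq_hz, sampling_rate) {
  vapply(freq_hz, function(f) {
    w <- 2 * pi * f / sampling_rate
    Mod(sum(h * exp(-1i * w * (seq_along(h) - 1))))
  }, numeric(1))
}

# zero-phase FIR application to the columns of a matrix: reflect-pad by
# 3 x order, then convolve with the filter's autocorrelation (the exact
# forward-backward response, |H(w)|^2) via FFT.  The pad exceeds the
# two-sided support of the autocorrelation, so circular wraparound never
# reaches the retained samples and the result matches explicit
# forward-backward filtering to numerical precision.
filtfilt_fir <- function(m, h) {
  n <- nrow(m)
  n_taps <- length(h)
  if (n < 3 * n_taps) abort("sweep too short to filter")
  pad <- 3L * (n_taps - 1L)
  top <- m[(pad + 1L):2L, , drop = FALSE]
  bot <- m[(n - 1L):(n - pad), , drop = FALSE]
  x <- rbind(top, m, bot)
  nf <- stats::nextn(nrow(x) + 2L * n_taps, c(2, 3, 5))
  hh <- Mod(stats::fft(c(h, numeric(nf - n_taps))))^2
  y <- matrix(0, n, ncol(x))
  # bounded working set: transform a few thousand sweeps at a time
  block <- 2048L
  for (j0 in seq(1L, ncol(x), by = block)) {
    jj <- j0:min(j0 + block - 1L, ncol(x))
    xp <- rbind(x[, jj, drop = FALSE], matrix(0, nf - nrow(x), length(jj)))
    yb <- Re(stats::mvfft(stats::mvfft(xp) * hh, inverse = TRUE)) / nf
    y[, jj] <- yb[(pad + 1L):(pad + n), , drop = FALSE]
  }
  y
}

#' Zero-phase low-pass filter sweeps
#'
#' Applies the least-squares FIR low-pass of [design_lowpass_fir()] forward
#' then backward (zero net phase, squared magnitude response) to every sweep.
#' Edges are handled by reflect-padding with three filter orders of samples,
#' which keeps onset transients out of the analysis window.  Output traces
#' have the same length as the input; DC gain is within `1e-3` of 1.
#'
#' @param data a sweep table (see [check_sweeps()]).
#' @param cutoff_hz low-pass cutoff (default 300 Hz).
#' @param order FIR order (default 39).
#' @param transition transition-band fraction passed to
#'   [design_lowpass_fir()].
#' @return The sweep table with filtered `values`.
#' @export
lowpass_filter <- function(data, cutoff_hz = 300, order = 39, transition = 0.15) {
  check_sweeps(data)
  map_sweep_matrix(data, function(m, fs, onset_s) {
    if (cutoff_hz >= fs / 2) abort("cutoff must be below the Nyquist frequency")
    filtfilt_fir(m, design_lowpass_fir(cutoff_hz, fs, order, transition))
  })
}

#' Subtract the pre-stimulus baseline
#'
#' References each sweep to its mean potential over the pre-stimulus
#' interval `[0, onset_s)`, so the corrected baseline mean is 0.
#'
#' @param data a sweep table.
#' @return The sweep table with baseline-corrected `values`.
#' @export
baseline_correct <- function(data) {
  check_sweeps(data)
  if (any(data$onset_s <= 0)) abort("no baseline interval (onset_s must be > 0)")
  map_sweep_matrix(data, function(m, fs, onset_s) {
    n_base <- floor(onset_s * fs)
    if (n_base < 1) abort("no baseline interval (onset_s must be > 0)")
    sweep(m, 2, colMeans(m[seq_len(n_base), , drop = FALSE]))
  })
}

#' Extract amplitude and latency features from filtered sweeps
#'
#' Over the analysis window (default `[15, 100)` ms of sweep time, half
#' open): amplitude is the window maximum minus the window minimum (mV,
#' always `>= 0`); latency is the time from stimulus onset to the window
#' maximum (PSP) or minimum (LFP), in ms, with ties broken by the earliest
#' sample.  Flat windows are flagged `degenerate` (amplitude 0, latency at
#' the window start) rather than dropped, so batch runs survive dead sweeps.
#' Sweeps are expected to be filtered and baseline-corrected first.
#'
#' @param data a sweep table.
#' @param window analysis window `c(start, end)` in seconds of sweep time.
#' @return A tibble with one row per sweep: `cell_id`, `trial_id`,
#'   `signal_type`, `stimulus_freq_hz`, `amplitude_mv`, `latency_ms`,
#'   `degenerate`.
#' @export
extract_features <- function(data, window = c(0.015, 0.100)) {
  check_sweeps(data)
  amp <- lat <- rep(NA_real_, nrow(data))
  degen <- rep(FALSE, nrow(data))
  len <- lengths(data$values)
  grp <- paste(data$sampling_rate, len, data$onset_s)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    fs <- data$sampling_rate[idx[1]]
    n <- len[idx[1]]
    t <- (seq_len(n) - 1) / fs
    sel <- which(t >= window[1] & t < window[2])
    if (length(sel) == 0 || window[2] > n / fs + 1e-12) {
      abort("analysis window outside sweep")
    }
    m <- matrix(unlist(data$values[idx], use.names = FALSE), nrow = n)
    wmat <- t(m[sel, , drop = FALSE]) # rows = sweeps, cols = window samples
    imax <- max.col(wmat, ties.method = "first")
    imin <- max.col(-wmat, ties.method = "first")
    vmax <- wmat[cbind(seq_len(nrow(wmat)), imax)]
    vmin <- wmat[cbind(seq_len(nrow(wmat)), imin)]
    amp[idx] <- vmax - vmin
    is_lfp <- data$signal_type[idx] == "LFP"
    iext <- ifelse(is_lfp, imin, imax)
    lat[idx] <- (t[sel][iext] - data$onset_s[idx]) * 1000
    degen[idx] <- vmax == vmin
  }
  tibble(
    cell_id = data$cell_id,
    trial_id = data$trial_id,
    signal_type = data$signal_type,
    stimulus_freq_hz = data$stimulus_freq_hz,
    amplitude_mv = amp,
    latency_ms = lat,
    degenerate = degen
  )
}

#' Plain-text sweep store
#'
#' Writes one CSV per cell (`cell_<id>.csv`) with the per-trial metadata
#' columns followed by the sample columns `v1..vn`; `read_sweep_store()`
#' reads every such file back into a sweep table.
#'
#' @param data a sweep table.
#' @param dir store directory (created if needed).
#' @return The directory (write) or a sweep table (read).
#' @export
write_sweep_store <- function(data, dir) {
  check_sweeps(data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cid in unique(data$cell_id)) {
    rows <- data[data$cell_id == cid, ]
    samples <- do.call(rbind, rows$values)
    colnames(samples) <- paste0("v", seq_len(ncol(samples)))
    flat <- dplyr::bind_cols(
      rows[, c("trial_id", "signal_type", "stimulus_freq_hz",
               "sampling_rate", "onset_s")],
      as_tibble(samples)
    )
    readr::write_csv(flat, file.path(dir, paste0("cell_", cid, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_sweep_store
#' @export
read_sweep_store <- function(dir) {
  files <- list.files(dir, pattern = "^cell_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0) abort(sprintf("no cell_*.csv files found in '%s'", dir))
  purrr::map_dfr(files, function(f) {
    cid <- sub("^cell_(.*)\\.csv$", "\\1", basename(f))
    flat <- readr::read_csv(f, col_types = readr::cols(
      trial_id = readr::col_integer(),
      signal_type = readr::col_character(),
      .default = readr::col_double()
    ))
    meta <- c("trial_id", "signal_type", "stimulus_freq_hz",
              "sampling_rate", "onset_s")
    vals <- as.matrix(flat[, setdiff(names(flat), meta)])
    tibble(
      cell_id = cid,
      trial_id = flat$trial_id,
      signal_type = flat$signal_type,
      stimulus_freq_hz = flat$stimulus_freq_hz,
      sampling_rate = flat$sampling_rate,
      onset_s = flat$onset_s,
      values = asplit(unname(vals), 1)
    )
  })
}

#' Importer stub for the original whole-cell / field-potential recordings
#'
#' The real tone-evoked dataset this package's analyses are designed around
#' is distributed through a registration-gated archive and its on-disk
#' layout is not publicly specified, so no reader is implemented.  This stub
#' documents the intended entry point and fails with a pointer to the
#' supported plain-text store.
#'
#' @param path path to a raw recording file.
#' @export
read_crcns_sweeps <- function(path) {
  abort(paste(
    "importing the original recordings is not implemented:",
    "the raw file layout is not publicly specified.",
    "Use read_sweep_store() / write_sweep_store() for the supported store."
  ))
}

#' Plot a handful of sweeps
#'
#' @param data a sweep table.
#' @param n_max maximum number of sweeps to draw.
#' @return A ggplot of voltage against time, faceted by signal type.
#' @export
plot_sweeps <- function(data, n_max = 12) {
  check_sweeps(data)
  rows <- utils::head(data, n_max)
  long <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    v <- rows$values[[i]]
    tibble(
      cell_id = rows$cell_id[i], trial_id = rows$trial_id[i],
      signal_type = rows$signal_type[i],
      time_ms = 1000 * (seq_along(v) - 1) / rows$sampling_rate[i],
      mv = v
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$mv,
                                     group = interaction(.data$cell_id, .data$trial_id),
                                     colour = factor(.data$trial_id))) +
    ggplot2::geom_line(alpha = 0.7, show.legend = FALSE) +
    ggplot2::facet_wrap(~signal_type, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "potential (mV)") +
    ggplot2::theme_minimal()
}
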