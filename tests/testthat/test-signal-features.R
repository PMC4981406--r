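test_that("the designed low-pass has unit DC gain and a deep stopband", {
  h <- design_lowpass_fir(300, 4000, order = 39)
  expect_length(h, 40)
  expect_equal(h, rev(h), tolerance = 1e-12) # linear phase
  expect_lt(abs(fir_gain(h, 0, 4000) - 1), 1e-3)
  expect_lt(fir_gain(h, 1000, 4000), 0.05)
  expect_error(design_lowpass_fir(2500, 4000), "Nyquist")
})

test_that("a constant sweep passes through the filter unchanged", {
  sw <- make_sweep(rep(2, 440))
  out <- lowpass_filter(sw)$values[[1]]
  expect_true(all(abs(out - 2) < 1e-3))
})

test_that("two-pass sinusoid gains match the filter's own magnitude response", {
  fs <- 4000
  t <- (0:7999) / fs
  h <- design_lowpass_fir(300, fs)
  for (f0 in c(50, 500)) {
    sw <- make_sweep(sin(2 * pi * f0 * t))
    out <- lowpass_filter(sw)$values[[1]]
    mid <- out[2000:6000] # steady state, away from edges
    measured <- (max(mid) - min(mid)) / 2
    predicted <- fir_gain(h, f0, fs)^2
    if (f0 < 300) {
      expect_lt(abs(measured - predicted) / predicted, 0.02)
      expect_lt(abs(measured - 1), 0.02)
    } else {
      expect_lte(measured, predicted + 1e-6)
    }
  }
})

test_that("filtering is zero phase: a symmetric pulse keeps its extremum time", {
  fs <- 4000
  t <- (0:439) / fs
  v <- exp(-((t - 0.055) / 0.006)^2)
  sw <- make_sweep(v)
  out <- lowpass_filter(sw)$values[[1]]
  expect_equal(which.max(out), which.max(v), tolerance = 1)
})

test_that("short sweeps are rejected with a clear error", {
  expect_error(lowpass_filter(make_sweep(rep(0, 100))), "too short")
})

test_that("baseline correction zeroes the pre-stimulus mean and is a pure shift", {
  fs <- 4000
  t <- (0:439) / fs
  v <- 1.5 + 5 * exp(-((t - 0.055) / 0.01)^2)
  sw <- make_sweep(v)
  out <- baseline_correct(sw)$values[[1]]
  expect_lt(abs(mean(out[seq_len(60)])), 1e-12) # first 15 ms at 4 kHz
  expect_equal(which.max(out), which.max(v))
  expect_equal(max(out), 5, tolerance = 1e-6)

  shifted <- baseline_correct(make_sweep(v + 42))$values[[1]]
  expect_equal(shifted, out, tolerance = 1e-12)
  expect_error(baseline_correct(make_sweep(v, onset_s = 0)), "baseline")
})

test_that("constant traces baseline-correct to zero", {
  out <- baseline_correct(make_sweep(rep(3, 440)))$values[[1]]
  expect_true(all(out == 0))
})

test_that("amplitude and latency come out exactly on constructed bumps", {
  fs <- 4000
  t <- (0:439) / fs
  psp <- make_sweep(5 * exp(-((t - 0.055) / 0.010)^2), "PSP")
  f1 <- psp |> lowpass_filter() |> baseline_correct() |> extract_features()
  expect_equal(f1$amplitude_mv, 5, tolerance = 0.01 * 5)
  expect_equal(f1$latency_ms, 40)

  lfp <- make_sweep(-3 * exp(-((t - 0.030) / 0.008)^2), "LFP")
  f2 <- lfp |> lowpass_filter() |> baseline_correct() |> extract_features()
  expect_equal(f2$amplitude_mv, 3, tolerance = 0.01 * 3)
  expect_equal(f2$latency_ms, 15)
})

test_that("flat windows are flagged degenerate with zero amplitude and latency", {
  f <- extract_features(make_sweep(rep(0, 440)))
  expect_equal(f$amplitude_mv, 0)
  expect_equal(f$latency_ms, 0)
  expect_true(f$degenerate)
})

test_that("the full chain is invariant to a constant offset and keeps bounds", {
  withr::with_seed(11, {
    v <- rnorm(440, sd = 0.2)
    v[200:260] <- v[200:260] + 3
    a <- make_sweep(v) |> lowpass_filter() |> baseline_correct() |> extract_features()
    b <- make_sweep(v + 7) |> lowpass_filter() |> baseline_correct() |> extract_features()
    expect_equal(a$amplitude_mv, b$amplitude_mv, tolerance = 1e-9)
    expect_equal(a$latency_ms, b$latency_ms)
    expect_gte(a$amplitude_mv, 0)
    expect_true(a$latency_ms >= 0 && a$latency_ms <= 85)
  })
})

test_that("windows outside the sweep are rejected", {
  expect_error(extract_features(make_sweep(rep(0, 440)), window = c(0.015, 0.2)),
               "window")
})

test_that("the sweep store round-trips through per-cell CSV files", {
  withr::with_seed(2, {
    sw <- dplyr::bind_rows(
      make_sweep(rnorm(440), cell_id = "c01", trial_id = 1L),
      make_sweep(rnorm(440), cell_id = "c01", trial_id = 2L, signal_type = "LFP"),
      make_sweep(rnorm(440), cell_id = "c02", trial_id = 1L, freq = 4000)
    )
  })
  dir <- withr::local_tempdir()
  write_sweep_store(sw, dir)
  expect_length(list.files(dir, pattern = "^cell_"), 2)
  back <- read_sweep_store(dir)
  back <- back[order(back$cell_id, back$trial_id), ]
  expect_equal(nrow(back), 3)
  for (i in 1:3) {
    expect_equal(as.numeric(back$values[[i]]), as.numeric(sw$values[[i]]),
                 tolerance = 1e-9)
  }
  expect_equal(back$stimulus_freq_hz, sw$stimulus_freq_hz)
})

test_that("the raw-recording importer is an explicit stub", {
  expect_error(read_crcns_sweeps("whatever.dat"), "not implemented")
})
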