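test_that("average re-referencing zeroes the cross-channel mean and is idempotent", {
  set.seed(1)
  rec <- make_recording(matrix(rnorm(400), 4, 100) + c(1, 2, 3, 4))
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  again <- rereference_average(out)
  expect_equal(again$data, out$data, tolerance = 1e-12)
  one <- make_recording(matrix(rnorm(100), 1), n_channels = 8)
  one$montage <- NULL
  expect_error(rereference_average(one), "2 channels")
})

test_that("band-pass keeps the passband, rejects the stopband and removes DC", {
  fs <- 256; n <- fs * 8
  cfg <- preproc_config(target_fs = 128)
  tone <- function(f) make_recording(rbind(sine_wave(f, fs, n),
                                           sine_wave(f, fs, n, phase = 1)),
                                     fs = fs, n_channels = 8)
  mid <- (n / 4):(3 * n / 4)  # avoid filter edge transients
  in10 <- bandpass_chebyshev2(tone(10), cfg)
  expect_equal(max(abs(in10$data[1, mid])), 1, tolerance = 0.05)
  in60 <- bandpass_chebyshev2(tone(60), cfg)
  atten_db <- -20 * log10(max(abs(in60$data[1, mid])))
  expect_gt(atten_db, 40)
  dc <- make_recording(matrix(2, 2, n), fs = fs, n_channels = 8)
  out <- bandpass_chebyshev2(dc, cfg)
  expect_lt(max(abs(out$data[, mid])), 0.05)
  bad <- preproc_config(band_low = 1, band_high = 32, target_fs = 128)
  lowfs <- make_recording(matrix(rnorm(2 * 50), 2), fs = 50, n_channels = 8)
  expect_error(bandpass_chebyshev2(lowfs, bad), "Nyquist|twice")
})

test_that("resampling preserves length ratios, waveforms and trial spans", {
  fs <- 512; n <- 512
  rec <- make_recording(rbind(sine_wave(10, fs, n), sine_wave(5, fs, n)),
                        fs = fs, n_channels = 8,
                        trials = data.frame(start = 1L, end = 512L,
                                            label = 1L))
  out <- resample_to(rec, 128)
  expect_equal(ncol(out$data), 128)
  expect_equal(out$fs, 128)
  expect_equal(out$trials$start, 1)
  expect_equal(out$trials$end, 128)
  ref <- sine_wave(10, 128, 128)
  mid <- 16:112
  expect_gt(cor(out$data[1, mid], ref[mid]), 0.99)
  expect_identical(resample_to(rec, fs), rec)
  expect_error(resample_to(rec, 1024), "upsampling")
})

test_that("per-trial standardization gives mean 0 / var 1 independently per trial", {
  set.seed(2)
  data <- cbind(matrix(rnorm(3 * 100, mean = 5, sd = 3), 3),
                matrix(rnorm(3 * 100, mean = -2, sd = 0.1), 3))
  rec <- make_recording(data, n_channels = 8,
                        trials = data.frame(start = c(1L, 101L),
                                            end = c(100L, 200L),
                                            label = c(0L, 1L)))
  out <- normalize_trial(rec)
  for (tr in 1:2) {
    seg <- out$data[, out$trials$start[tr]:out$trials$end[tr]]
    expect_equal(rowMeans(seg), rep(0, 3), tolerance = 1e-6)
    expect_equal(apply(seg, 1, var), rep(1, 3), tolerance = 1e-6)
  }
  again <- normalize_trial(out)
  expect_equal(again$data, out$data, tolerance = 1e-8)
  rec$data[2, 101:200] <- 7  # constant channel in trial 2 only
  expect_error(normalize_trial(rec), "trial 2")
})

test_that("alpha-band extraction passes 10 Hz, rejects 4 Hz, reduces broadband variance", {
  fs <- 128; n <- fs * 8
  mid <- (n / 4):(3 * n / 4)
  t10 <- extract_band(make_recording(rbind(sine_wave(10, fs, n)),
                                     fs = fs, n_channels = 8), 8, 13)
  expect_equal(max(abs(t10$data[1, mid])), 1, tolerance = 0.05)
  t4 <- extract_band(make_recording(rbind(sine_wave(4, fs, n)),
                                    fs = fs, n_channels = 8), 8, 13)
  expect_gt(-20 * log10(max(abs(t4$data[1, mid]))), 20)
  set.seed(3)
  wide <- make_recording(matrix(rnorm(2 * n), 2), fs = fs, n_channels = 8)
  narrow <- extract_band(wide, 8, 13)
  expect_lt(var(narrow$data[1, ]), var(wide$data[1, ]))
  expect_error(extract_band(wide, 13, 8), "invalid band")
})

test_that("window counts follow the closed-form formula for all seven window sizes", {
  fs <- 128
  trial_n <- 60 * fs
  set.seed(4)
  rec <- make_recording(matrix(rnorm(4 * trial_n), 4), fs = fs,
                        n_channels = 8,
                        trials = data.frame(start = 1L, end = trial_n,
                                            label = 0L))
  for (w in c(0.1, 0.2, 0.5, 1, 2, 5, 10)) {
    wins <- segment_windows(rec, preproc_config(window_s = w))
    win_samp <- round(w * fs)
    expect_equal(length(wins), floor((trial_n - win_samp) / win_samp) + 1)
    expect_equal(ncol(wins[[1]]$data), win_samp)
    expect_equal(wins[[1]]$label, 0L)
  }
  # fractional window length rounds to the nearest sample: 0.1 s -> 13
  w01 <- segment_windows(rec, preproc_config(window_s = 0.1))
  expect_equal(ncol(w01[[1]]$data), 13)
})

test_that("a 6-minute trial at 128 Hz yields 360 one-second windows", {
  fs <- 128
  n <- 360 * fs
  rec <- make_recording(matrix(0, 4, n) + rnorm(n), fs = fs, n_channels = 8,
                        trials = data.frame(start = 1L, end = n, label = 1L))
  wins <- segment_windows(rec, preproc_config(window_s = 1, stride_s = 1))
  expect_length(wins, 360)
})

test_that("windows longer than the trial produce a warning and no windows", {
  rec <- make_recording(matrix(rnorm(4 * 64), 4), fs = 128, n_channels = 8,
                        trials = data.frame(start = 1L, end = 64L,
                                            label = 0L))
  expect_warning(wins <- segment_windows(rec, preproc_config(window_s = 1)),
                 "shorter than one window")
  expect_length(wins, 0)
})

test_that("the full chain is approximately idempotent", {
  spec <- synth_spec(n_channels = 8, trial_length_s = 2, n_trials_per_class = 2,
                     seed = 9)
  rec <- generate_dataset(spec)
  cfg <- preproc_config()
  once <- preprocess_recording(rec, cfg)
  twice <- preprocess_recording(once, cfg)
  # re-reference and normalization are exactly idempotent; the second filter
  # pass only nibbles at band edges
  expect_gt(cor(as.vector(once$data), as.vector(twice$data)), 0.98)
})
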