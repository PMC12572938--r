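#' Preprocessing configuration
#'
#' Parameters of the EEG signal chain: average re-reference, zero-phase
#' Chebyshev type II band-pass (1-32 Hz, 6th order by default), polyphase
#' resampling to 128 Hz, per-trial standardization, and sliding decision
#' windows. Stride defaults to the window length (non-overlapping windows).
#'
#' @param band_low,band_high Band-pass edges in Hz.
#' @param filter_order Overall band-pass filter order (even, >= 2).
#' @param target_fs Output sampling rate in Hz.
#' @param stopband_atten_db Chebyshev-II stopband attenuation in dB.
#' @param window_s Decision-window length in seconds.
#' @param stride_s Window stride in seconds; `NULL` means `window_s`.
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(band_low = 1, band_high = 32, filter_order = 6,
                           target_fs = 128, stopband_atten_db = 40,
                           window_s = 1, stride_s = NULL) {
  if (is.null(stride_s)) stride_s <- window_s
  cfg <- list(band_low = band_low, band_high = band_high,
              filter_order = as.integer(filter_order), target_fs = target_fs,
              stopband_atten_db = stopband_atten_db,
              window_s = window_s, stride_s = stride_s)
  class(cfg) <- "preproc_config"
  if (!(band_low > 0 && band_low < band_high && band_high < target_fs / 2)) {
    stop("need 0 < band_low < band_high < target_fs/2")
  }
  if (cfg$filter_order < 2 || cfg$filter_order %% 2 != 0) {
    stop("filter_order must be even and >= 2")
  }
  if (window_s <= 0 || stride_s <= 0) stop("window_s and stride_s must be positive")
  cfg
}

#' Re-reference a recording to the common average
#'
#' Subtracts, at each sample, the mean over all channels, so the
#' cross-channel mean is zero everywhere. Idempotent.
#'
#' @param rec An `eeg_recording`.
#' @return The re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  validate_eeg_recording(rec)
  if (nrow(rec$data) < 2) stop("average re-reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Zero-phase Chebyshev type II band-pass filter
#'
#' Applies a band-pass Chebyshev type II filter forward and backward
#' (zero-phase) to every channel. A type II design is specified by its
#' stopband edges; these are placed at `band_low / 2` and
#' `1.5 * band_high` so that the requested `[band_low, band_high]` passband
#' itself is transmitted at unity gain and the transition bands lie outside
#' it. Stopband attenuation is at least `stopband_atten_db` (doubled by the
#' forward-backward pass), and DC is removed.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preproc_config()].
#' @return The filtered `eeg_recording`.
#' @export
bandpass_chebyshev2 <- function(rec, cfg = preproc_config()) {
  validate_eeg_recording(rec)
  if (cfg$band_high >= rec$fs / 2) stop("band_high must be below Nyquist")
  if (rec$fs <= 2 * cfg$band_high) stop("fs must exceed twice band_high")
  ws <- c(cfg$band_low / 2, min(1.5 * cfg$band_high, 0.98 * rec$fs / 2))
  filt <- signal::cheby2(cfg$filter_order / 2, cfg$stopband_atten_db,
                         ws / (rec$fs / 2), "pass")
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(filt, x)))
  rec
}

#' Downsample a recording with zero-phase anti-aliased resampling
#'
#' Applies a zero-phase (forward-backward Butterworth) anti-aliasing
#' low-pass at 90% of the target Nyquist frequency, then evaluates the
#' band-limited signal at the new sample times by spline interpolation.
#' Zero-phase filtering keeps the resampler free of group delay, matching
#' the pipeline's zero-phase band-pass convention. Only downsampling is
#' supported. Trial boundaries are rescaled consistently (floor for starts,
#' ceiling for ends). Output length is `round(n * target_fs / fs)`.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Output sampling rate, Hz.
#' @return The resampled `eeg_recording`.
#' @export
resample_to <- function(rec, target_fs = 128) {
  validate_eeg_recording(rec)
  if (target_fs > rec$fs) stop("upsampling is not supported")
  if (target_fs == rec$fs) return(rec)
  n_in <- ncol(rec$data)
  n_out <- round(n_in * target_fs / rec$fs)
  aa <- signal::butter(4, 0.9 * target_fs / rec$fs, "low")
  t_in <- (seq_len(n_in) - 1) / rec$fs
  t_out <- (seq_len(n_out) - 1) / target_fs
  out <- matrix(0, nrow(rec$data), n_out)
  for (ch in seq_len(nrow(rec$data))) {
    sm <- signal::filtfilt(aa, rec$data[ch, ])
    out[ch, ] <- stats::spline(t_in, sm, xout = t_out, method = "fmm")$y
  }
  sc <- target_fs / rec$fs
  trials <- rec$trials
  trials$start <- pmax(1L, floor((trials$start - 1) * sc) + 1L)
  trials$end <- pmin(n_out, ceiling(trials$end * sc))
  new_eeg_recording(out, target_fs, rec$montage, trials)
}

#' Standardize each trial to zero mean and unit variance
#'
#' Per channel and per trial, subtracts the mean and divides by the standard
#' deviation. Samples outside any trial are left untouched.
#'
#' @param rec An `eeg_recording` with at least one trial.
#' @return The standardized `eeg_recording`.
#' @export
normalize_trial <- function(rec) {
  validate_eeg_recording(rec)
  for (i in seq_len(nrow(rec$trials))) {
    idx <- rec$trials$start[i]:rec$trials$end[i]
    if (length(idx) < 2) stop("trial ", i, " has fewer than 2 samples")
    seg <- rec$data[, idx, drop = FALSE]
    mu <- rowMeans(seg)
    sdv <- sqrt(rowSums((seg - mu)^2) / (length(idx) - 1))
    if (any(sdv == 0)) {
      ch <- which(sdv == 0)[1]
      stop("constant channel ", rec$montage$channel_names[ch],
           " in trial ", i, " cannot be standardized")
    }
    rec$data[, idx] <- (seg - mu) / sdv
  }
  rec
}

#' Restrict a recording to one frequency band
#'
#' Zero-phase band-pass copy of the recording (Chebyshev type II, same
#' design convention as [bandpass_chebyshev2()]: stopband edges 20% outside
#' the requested band so the band itself passes at unity gain). The default
#' band is alpha, 8-13 Hz.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz.
#' @param order Filter order.
#' @return Band-limited `eeg_recording`.
#' @export
extract_band <- function(rec, low = 8, high = 13, order = 6) {
  validate_eeg_recording(rec)
  if (!(low < high && high < rec$fs / 2)) stop("invalid band for this sampling rate")
  ws <- c(low / 1.25, min(high * 1.25, 0.98 * rec$fs / 2))
  filt <- signal::cheby2(order / 2, 30, ws / (rec$fs / 2), "pass")
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(filt, x)))
  rec
}

#' Cut a recording into sliding decision windows
#'
#' Per trial, windows of `round(window_s * fs)` samples are extracted every
#' `round(stride_s * fs)` samples; each window inherits the trial's label.
#' The window count per trial is
#' `floor((trial_samples - win_samples) / stride_samples) + 1`. Trials
#' shorter than one window yield zero windows, with a warning.
#'
#' @param rec An `eeg_recording` with labeled trials.
#' @param cfg A [preproc_config()] providing `window_s` and `stride_s`.
#' @return List of `eeg_window` objects (`data`, `fs`, `label`,
#'   `source_trial`).
#' @export
segment_windows <- function(rec, cfg = preproc_config()) {
  validate_eeg_recording(rec)
  win <- round(cfg$window_s * rec$fs)
  stride <- round(cfg$stride_s * rec$fs)
  if (win < 1) stop("window shorter than one sample")
  if (stride < 1) stop("stride shorter than one sample")
  out <- list()
  for (i in seq_len(nrow(rec$trials))) {
    n_tr <- rec$trials$end[i] - rec$trials$start[i] + 1
    if (n_tr < win) {
      warning("trial ", i, " shorter than one window; skipped")
      next
    }
    n_win <- floor((n_tr - win) / stride) + 1
    for (w in seq_len(n_win)) {
      s <- rec$trials$start[i] + (w - 1) * stride
      out[[length(out) + 1]] <- structure(
        list(data = rec$data[, s:(s + win - 1), drop = FALSE], fs = rec$fs,
             label = rec$trials$label[i], source_trial = i),
        class = "eeg_window")
    }
  }
  out
}

#' Full preprocessing chain
#'
#' Applies, in order: average re-reference, Chebyshev-II band-pass,
#' resampling to `cfg$target_fs`, and per-trial standardization.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preproc_config()].
#' @return The preprocessed `eeg_recording`.
#' @export
preprocess_recording <- function(rec, cfg = preproc_config()) {
  rec <- rereference_average(rec)
  rec <- bandpass_chebyshev2(rec, cfg)
  rec <- resample_to(rec, cfg$target_fs)
  normalize_trial(rec)
}
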