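#' Specification for a synthetic EEG dataset
#'
#' Defines the study conditions for the synthetic generator: band-limited
#' oscillatory bursts in the canonical EEG bands (delta 0.5-4 Hz, theta
#' 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz, gamma > 30 Hz) on top of pink
#' (1/f^beta) background noise, with a class-dependent left:right hemispheric
#' asymmetry of the alpha-burst amplitude. Two classes are generated:
#' class 0 uses `alpha_asymmetry[1]`, class 1 uses `alpha_asymmetry[2]`.
#'
#' @param n_channels Electrode count (8, 32 or 64; passed to [make_montage()]).
#' @param fs Sampling rate in Hz. Must exceed twice the highest band edge used.
#' @param trial_length_s Trial duration in seconds.
#' @param n_trials_per_class Trials generated per class label.
#' @param band_powers Named numeric vector of burst amplitudes (signal units)
#'   per band; names among `"delta","theta","alpha","beta","gamma"`.
#' @param alpha_asymmetry Length-2 positive numeric: left:right alpha
#'   amplitude ratio for class 0 and class 1.
#' @param noise_exponent Pink-noise spectral exponent beta in 1/f^beta.
#' @param noise_amplitude Standard deviation of the pink background noise.
#' @param seed Integer RNG seed; the generator is fully deterministic given
#'   the settings object.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_channels = 32, fs = 128, trial_length_s = 4,
                       n_trials_per_class = 20,
                       band_powers = c(delta = 1, theta = 0.8, alpha = 1,
                                       beta = 0.5, gamma = 0.3),
                       alpha_asymmetry = c(1.5, 0.67),
                       noise_exponent = 1, noise_amplitude = 0.7,
                       seed = 1L) {
  spec <- list(n_channels = n_channels, fs = fs,
               trial_length_s = trial_length_s,
               n_trials_per_class = n_trials_per_class,
               band_powers = band_powers,
               alpha_asymmetry = alpha_asymmetry,
               noise_exponent = noise_exponent,
               noise_amplitude = noise_amplitude,
               seed = as.integer(seed))
  class(spec) <- "synth_spec"
  validate_synth_spec(spec)
  spec
}

# band edges in Hz (gamma capped below Nyquist at generation time)
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 45))
}

validate_synth_spec <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$trial_length_s <= 0) stop("trial_length_s must be positive")
  if (any(spec$alpha_asymmetry <= 0)) stop("alpha_asymmetry must be positive")
  if (length(spec$alpha_asymmetry) != 2) stop("alpha_asymmetry needs one ratio per class")
  bands <- eeg_bands()
  used <- names(spec$band_powers)[spec$band_powers > 0]
  bad <- setdiff(used, names(bands))
  if (length(bad) > 0) stop("unknown band(s): ", paste(bad, collapse = ", "))
  if (length(used) > 0) {
    top <- max(vapply(bands[used], function(b) min(b[2], spec$fs / 2 * 0.98),
                      numeric(1)))
    if (spec$fs <= 2 * top * 0.999) {
      stop("fs must exceed twice the highest band edge used")
    }
  }
  invisible(spec)
}

# independent sub-streams so bursts are seed-stable under noise changes
derive_seed <- function(seed, tag) {
  as.integer((as.double(seed) * 7919 + tag * 104729) %% 2147483647)
}

# pink noise via spectral shaping of white Gaussian noise
pink_noise <- function(n, exponent, fs) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)          # two-sided frequency axis
  scale <- ifelse(f <= 0, 0, f^(-exponent / 2))
  x <- Re(stats::fft(spec * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# One band-limited amplitude-modulated sinusoid burst. The waxing-waning
# envelope runs at 1-3 Hz (spindle-like), fast enough that every decision
# window >= 0.5 s averages over it, so per-window band power stays close to
# amplitude^2 / 2 and the hemispheric power ratio is a stable ground truth.
# The carrier is drawn from the band interior (15% margin per edge) so the
# modulation sidebands at carrier +/- mod_f stay essentially in band.
band_burst <- function(n, fs, band, amplitude) {
  lo <- band[1]; hi <- min(band[2], fs / 2 * 0.98)
  bw <- hi - lo
  freq <- stats::runif(1, lo + 0.15 * bw, hi - 0.15 * bw)
  phase <- stats::runif(1, 0, 2 * pi)
  mod_f <- stats::runif(1, 1, 3)
  mod_ph <- stats::runif(1, 0, 2 * pi)
  t <- (seq_len(n) - 1) / fs
  env <- 1 + 0.4 * sin(2 * pi * mod_f * t + mod_ph)
  amplitude * env / sqrt(1.08) * sin(2 * pi * freq * t + phase)
}

#' Generate one labeled synthetic EEG recording
#'
#' Each trial is a sum over bands of amplitude-modulated sinusoid bursts with
#' per-trial, per-channel random frequency and phase, plus pink 1/f^beta
#' background noise. The alpha-band amplitude on left-hemisphere channels is
#' multiplied by the class's `alpha_asymmetry` ratio (midline channels get the
#' mean of the left and right gains). Bursts and noise draw from separate
#' seeded RNG streams, so burst waveforms are stable under changes of the
#' noise level.
#'
#' @param spec A [synth_spec()].
#' @param class_label Integer class label (0 or 1) selecting the asymmetry.
#' @return An `eeg_recording`: list with `data` (channels x samples matrix),
#'   `fs`, `montage`, and `trials` (data.frame of start/end samples + label).
#' @export
generate_recording <- function(spec, class_label) {
  validate_synth_spec(spec)
  stopifnot(class_label %in% c(0L, 1L))
  montage <- make_montage(spec$n_channels)
  n_trial <- round(spec$trial_length_s * spec$fs)
  n_trials <- spec$n_trials_per_class
  nch <- spec$n_channels
  data <- matrix(0, nch, n_trial * n_trials)
  hemi <- channel_hemisphere(montage$channel_names)
  asym <- spec$alpha_asymmetry[class_label + 1L]
  alpha_gain <- ifelse(hemi == "left", asym,
                       ifelse(hemi == "right", 1, (asym + 1) / 2))
  bands <- eeg_bands()
  burst_seed <- derive_seed(spec$seed, 11L + class_label)
  noise_seed <- derive_seed(spec$seed, 23L + class_label)

  set.seed(burst_seed)
  for (tr in seq_len(n_trials)) {
    cols <- ((tr - 1) * n_trial + 1):(tr * n_trial)
    for (ch in seq_len(nch)) {
      x <- numeric(n_trial)
      for (bn in names(spec$band_powers)) {
        amp <- spec$band_powers[[bn]]
        if (amp <= 0) next
        if (bn == "alpha") amp <- amp * alpha_gain[ch]
        x <- x + band_burst(n_trial, spec$fs, bands[[bn]], amp)
      }
      data[ch, cols] <- x
    }
  }
  if (spec$noise_amplitude > 0) {
    set.seed(noise_seed)
    for (ch in seq_len(nch)) {
      data[ch, ] <- data[ch, ] +
        spec$noise_amplitude * pink_noise(ncol(data), spec$noise_exponent, spec$fs)
    }
  }
  trials <- data.frame(start = (seq_len(n_trials) - 1) * n_trial + 1,
                       end = seq_len(n_trials) * n_trial,
                       label = rep(as.integer(class_label), n_trials))
  new_eeg_recording(data, spec$fs, montage, trials)
}

#' Generate a balanced two-class synthetic EEG dataset
#'
#' Generates `n_trials_per_class` trials for each class with
#' [generate_recording()] and interleaves them in a seed-determined shuffled
#' order. Labels are exactly balanced.
#'
#' @param spec A [synth_spec()].
#' @return An `eeg_recording` whose `trials` hold both class labels.
#' @export
generate_dataset <- function(spec) {
  validate_synth_spec(spec)
  if (spec$n_trials_per_class < 1) stop("n_trials_per_class must be >= 1")
  rec0 <- generate_recording(spec, 0L)
  rec1 <- generate_recording(spec, 1L)
  n_trial <- rec0$trials$end[1] - rec0$trials$start[1] + 1
  set.seed(derive_seed(spec$seed, 37L))
  src <- c(rep(0L, spec$n_trials_per_class), rep(1L, spec$n_trials_per_class))
  ord <- sample(seq_along(src))
  src <- src[ord]
  within_idx <- integer(length(src))
  within_idx[src == 0L] <- seq_len(spec$n_trials_per_class)
  within_idx[src == 1L] <- seq_len(spec$n_trials_per_class)
  n_tot <- length(src)
  data <- matrix(0, spec$n_channels, n_trial * n_tot)
  for (i in seq_len(n_tot)) {
    rec <- if (src[i] == 0L) rec0 else rec1
    tr <- rec$trials[within_idx[i], ]
    data[, ((i - 1) * n_trial + 1):(i * n_trial)] <- rec$data[, tr$start:tr$end]
  }
  trials <- data.frame(start = (seq_len(n_tot) - 1) * n_trial + 1,
                       end = seq_len(n_tot) * n_trial,
                       label = src)
  new_eeg_recording(data, spec$fs, rec0$montage, trials)
}

new_eeg_recording <- function(data, fs, montage, trials) {
  rec <- list(data = data, fs = fs, montage = montage, trials = trials)
  class(rec) <- "eeg_recording"
  validate_eeg_recording(rec)
  rec
}

validate_eeg_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!all(is.finite(rec$data))) stop("recording data must be finite")
  if (rec$fs <= 0) stop("fs must be positive")
  tr <- rec$trials
  if (nrow(tr) > 0) {
    if (any(tr$start < 1) || any(tr$end > ncol(rec$data)) ||
        any(tr$end < tr$start)) {
      stop("trial spans out of bounds")
    }
    o <- order(tr$start)
    if (any(tr$start[o][-1] <= tr$end[o][-nrow(tr)])) {
      stop("trials must not overlap")
    }
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " ch x ", ncol(x$data), " samples @ ",
      x$fs, " Hz, ", nrow(x$trials), " trials\n", sep = "")
  invisible(x)
}

#' Segment-averaged periodogram band power
#'
#' Average power of `x` inside `[low, high]` Hz, estimated by splitting the
#' signal into 50%-overlapping Hann-tapered segments and averaging their
#' periodograms (Welch's method).
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges in Hz.
#' @param n_seg Segment length in samples (default `min(length(x), 256)`).
#' @return Mean power spectral density summed over the band's frequency bins.
#' @export
band_power <- function(x, fs, low, high, n_seg = min(length(x), 256L)) {
  n <- length(x)
  n_seg <- min(n_seg, n)
  hop <- max(1L, n_seg %/% 2L)
  starts <- seq(1L, n - n_seg + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_seg) - 1) / (n_seg - 1))
  f <- (seq_len(n_seg) - 1) * fs / n_seg
  sel <- f >= low & f <= high & f <= fs / 2
  pw <- 0
  for (s in starts) {
    seg <- x[s:(s + n_seg - 1L)] * win
    p <- Mod(stats::fft(seg))^2 / sum(win^2) / n_seg
    pw <- pw + sum(p[sel])
  }
  pw / length(starts)
}
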