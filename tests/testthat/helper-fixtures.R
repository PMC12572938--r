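# Shared fixtures: everything is generated in code at test time.

tiny_cfg <- function(L = 2, wavelet_enabled = TRUE, T_steps = 2) {
  model_config(T_steps = T_steps, L = L, d = 8, patch_grid = 2,
               mlp_ratio = 2, n_classes = 2, heads = 2, map_hw = 8,
               wavelet_enabled = wavelet_enabled)
}

rand_encoded <- function(n, cfg, seed = 1) {
  set.seed(seed)
  x <- array(stats::rnorm(n * cfg$T * cfg$in_channels * cfg$map_hw^2),
             dim = c(n, cfg$T, cfg$in_channels, cfg$map_hw, cfg$map_hw))
  structure(list(x = x, labels = rep_len(c(0L, 1L), n), H = cfg$map_hw,
                 W = cfg$map_hw, T = cfg$T), class = "encoded_dataset")
}

subset_ds <- function(ds, idx) spikewavformer:::subset_encoded(ds, idx)

make_window <- function(data, fs = 128, label = 0L, source_trial = 1L) {
  structure(list(data = data, fs = fs, label = label,
                 source_trial = source_trial), class = "eeg_window")
}

make_recording <- function(data, fs = 128, n_channels = 8, trials = NULL) {
  if (is.null(trials)) {
    trials <- data.frame(start = 1L, end = ncol(data), label = 0L)
  }
  spikewavformer:::new_eeg_recording(data, fs, make_montage(n_channels),
                                     trials)
}

sine_wave <- function(freq, fs, n, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / fs + phase)
}

# literal step-by-step scalar evaluation of the LIF update equations;
# the independent oracle for the vectorized implementations
lif_oracle_scalar <- function(x, tau, v_th, v_reset, v0 = 0) {
  v <- v0
  s <- numeric(length(x))
  for (t in seq_along(x)) {
    h <- v + (x[t] - (v - v_reset)) / tau
    s[t] <- if (h - v_th >= 0) 1 else 0
    v <- if (s[t] == 1) v_reset else h
  }
  s
}
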