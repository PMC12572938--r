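# Example run configuration for the spikewavformer CLI.
# Every block is optional; omitted entries use the package defaults.

synth:
  n_channels: 32
  fs: 128
  trial_length_s: 4
  n_trials_per_class: 20
  alpha_asymmetry: [1.5, 0.67]
  noise_exponent: 1
  seed: 42

preprocess:
  band_low: 1
  band_high: 32
  filter_order: 6
  target_fs: 128
  window_s: 1

model:
  T_steps: 4
  L: 2
  d: 32
  patch_grid: 4
  heads: 8
  map_hw: 32
  wavelet_enabled: true

neuron:
  tau: 2
  v_th: 0.5
  v_reset: 0
  surrogate_alpha: 4

train:
  lr: 0.001
  epochs: 30
  batch_size: 16
  seed: 1
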