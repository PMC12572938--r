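---
title: "Spiking wavelet transformers for EEG classification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking wavelet transformers for EEG classification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikewavformer)
```

## The problem

Brain-computer interfaces classify short segments of multi-channel EEG —
a *decision window* of 0.1 to 10 s — into cognitive states such as an
attended-speaker side or an emotional dimension. Two practical obstacles
motivate this package's architecture: hand-crafted spectral features limit
generalization across tasks, and dense deep networks are too power-hungry
for wearable, battery-driven decoders. The model implemented here answers
both with a *spiking* transformer whose attention blocks carry an embedded
orthonormal wavelet branch: all inter-layer activations are binary spike
events (cheap accumulate operations on neuromorphic hardware), and a
single-level 2D Haar decomposition gives each encoder block an explicit,
invertible frequency-domain view of its feature maps.

## Signal path

1. **Preprocessing** (`preprocess_recording()`): common-average
   re-reference; zero-phase 6th-order Chebyshev type II band-pass with a
   1–32 Hz passband; zero-phase anti-aliased resampling to 128 Hz;
   per-trial, per-channel standardization to zero mean and unit variance.
   Decision windows are cut per trial with
   `floor((trial_samples - win_samples) / stride_samples) + 1` windows;
   fractional window lengths round to the nearest sample (0.1 s at 128 Hz
   is 13 samples). The stride defaults to the window length
   (non-overlapping) because the overlap is not a property of the method;
   it is exposed as a parameter.
2. **Topographic encoding** (`encode_windows()`): the alpha band
   (8–13 Hz) is extracted, each window is reduced to per-channel mean
   squared amplitude (`channel_power()`), and the channel values are
   interpolated onto a 32 × 32 head-plane image with inverse-distance
   weighting (power 2, 4 nearest electrodes). IDW was chosen over splines
   because it is linear in the channel values and cannot overshoot their
   range, which makes the encoder's contract testable
   (`min(values) <= pixel <= max(values)`). Each map is standardized over
   in-disc pixels and replicated over `T` simulation time steps (direct
   encoding; the first spiking layer performs the rate conversion
   implicitly).
3. **Network** (`spikewav_model()`): spiking patch splitting (stacked
   3 × 3 conv → batch norm → LIF → 2 × 2 max-pool stages) down to a
   `patch_grid²`-token sequence; `L` encoder blocks; global average
   pooling over tokens, mean over time steps, and a linear head. The head
   has no spiking layer so that real-valued class scores feed the
   cross-entropy objective.

## Neuron model

The leaky integrate-and-fire neuron follows the discrete update

$$H_t = V_{t-1} + \tfrac{1}{\tau}\bigl(X_t - (V_{t-1} - V_{reset})\bigr),
\qquad S_t = \Theta(H_t - V_{th}), \qquad
V_t = H_t(1 - S_t) + V_{reset}\,S_t,$$

with hard reset, threshold \(V_{th} = 0.5\), reset and initial potential 0,
and \(\tau = 2\) (the time constant is not fixed by the reference setting;
2 is the common surrogate-gradient default and is configurable). During
backpropagation the Heaviside derivative is replaced by the derivative of a
sharpened sigmoid, \(g(u) = \alpha\,\sigma(\alpha u)(1 - \sigma(\alpha u))\)
with \(\alpha = 4\); the forward pass stays exactly binary. "Sigmoid
surrogate" is read as *derivative of* the sigmoid — the universal
convention — rather than the sigmoid itself. The reset term is detached in
the backward pass (gradients do not flow through \(S_t\) inside the reset),
the standard practice that avoids a second discontinuity.

## The spiking wavelet attention block

Each block runs two parallel paths on its input spike tokens:

* **Attention path**: \(Q, K, V = \mathrm{LIF}(\mathrm{BN}(XW))\), then
  \(\mathrm{LIF}(s\,QK^\top V)\) with scaling \(s = 0.125\) and 8 heads
  (both inherited from common spiking-transformer practice; the reference
  setting defers its remaining architecture to that convention), then a
  projection \(\mathrm{LIF}(\mathrm{BN}(\mathrm{Linear}(\cdot)))\). There
  is no softmax: with binary \(Q, K, V\) every entry of \(QK^\top V\) is a
  non-negative integer and the scale only controls firing magnitude.
* **Wavelet path**: tokens are reshaped to their
  \(\sqrt N \times \sqrt N\) grid and Haar-analyzed into LL/LH/HL/HH
  sub-bands at half resolution. The LL, LH and HL bands are concatenated
  (3C channels), filtered by a learned 3 × 3 convolution to 4C channels,
  normalized, spiked, split into four spike-valued sub-bands, and
  Haar-synthesized back to full resolution. Leaving HH out of the filter
  input follows the block's defining equation literally (a plausible
  design: the highest-frequency corner carries mostly noise); because the
  synthesis stage needs four bands, the convolution maps 3C → 4C and its
  output quarters are interpreted as (LL, LH, HL, HH). An
  `include_hh` flag selects the alternative reading (4C → 4C) in case the
  omission was unintended.

The two outputs are concatenated channel-wise (2d), projected back to d,
normalized and spiked, so the block output is binary and shape-compatible
with the residual stream (`X' = SWSA(X) + X`). The concatenation doubles
the channel count while the residual requires d, so the 2d → d linear map
is a forced addition, absorbed into the final BN + LIF stage. Residual
sums operate on spike values and may reach small integers; no LIF is
applied after the add, matching spiking-transformer practice. With
`wavelet_enabled = FALSE` the block reduces exactly to plain spiking
self-attention, which is the ablation baseline.

The Haar pair uses the orthonormal normalization (gain 1/2 per 2 × 2
block in both directions), so analysis is an exact isometry —
\(\lVert W(x_1) - W(x_2)\rVert_2 = \lVert x_1 - x_2 \rVert_2\) — and
synthesis reconstructs to machine precision. Both properties are enforced
by tests, as is the linearity of both transforms. The wavelet convolution
starts as an LL identity passthrough (zeros elsewhere) so untrained
branches transmit the approximation band and inject no noise.

The wavelet transform operates on the token grid inside each block rather
than on the input image: the branch's output must be concatenated with the
attention output token-by-token, which fixes the operand to the
\(\sqrt N \times \sqrt N\) token layout.

## Training

Mini-batch Adam on mean softmax cross-entropy, with gradients flowing
through the surrogate at every spike and through time across the `T`
steps. An optional L1 penalty on the learned wavelet-filter coefficients
(`lambda_l1`) implements sparsity-promoting regularization of the wavelet
weights; it defaults to 0 because the reference experimental setup never
reports a penalty weight, so the plain cross-entropy objective is taken as
the canonical configuration. Per-epoch shuffling and the stratified 80/20
train/validation split draw from dedicated RNG streams, making a run
byte-reproducible for a fixed (seed, data, config) on a single thread; the
package pins its BLAS to one thread at load for the same reason. A NaN
loss aborts with the epoch, batch and learning rate in the message.

Batch normalization uses batch statistics during training (momentum 0.1,
eps 1e-5 running updates) and running statistics at evaluation, shared
across time steps by folding T into the batch axis — the standard
container convention for spiking transformers.

## Energy model

`energy_rate()` implements the neuromorphic energy comparison
\(\mathrm{rate} = \frac{AC}{MAC} \times \mathrm{SpikingRate} \times
\mathrm{TimeSteps}\), where the spiking rate is the fraction of ones over
all spike tensors, accumulated by instrumentation hooks on every LIF layer
(`measure_spike_rate()`). The per-operation ratio defaults to 1/17: an
accumulate is taken to be 17× cheaper than a multiply-accumulate, the only
direction of the published 17:1 figure under which a spiking network saves
energy, and it is exposed as a parameter. At the reported operating point
(rate 12.3%, T = 4) the formula gives an energy ratio of ≈ 0.0289, an
efficiency factor of ≈ 34.6× — comfortably above the claimed 7×; the
claimed figure cannot be re-derived exactly from its stated inputs, so the
package reports the formula's value. A zero spiking rate reports an
infinite-efficiency sentinel with a warning rather than dividing by zero.

## The synthetic task: what it does and does not show

`lateralized_alpha_dataset()` builds the desk-scale study conditions: a
32-channel, 128 Hz two-class dataset whose classes differ only in the
left:right hemispheric alpha-amplitude ratio (1.5 versus 0.67), the
classic lateralization signature of spatial auditory attention. Each trial
sums, per channel, band-limited amplitude-modulated sinusoid bursts in the
five canonical bands (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30,
gamma > 30 Hz; amplitudes 1, 0.8, 1, 0.5, 0.3) and pink 1/f background
noise (amplitude 0.7, exponent 1). Burst phases and frequencies are random
per channel and trial — full scalp coherence would be cancelled by the
common-average reference — and the burst envelope waxes and wanes at
1–3 Hz with depth 0.4, the spindle-like regime in which every decision
window of at least half a second averages over the envelope, so the
hemispheric power ratio is a stable per-window ground truth. Left
channels carry the class's alpha gain, right channels gain 1, midline the
mean of both. Bursts and noise use separate seeded RNG streams so the
burst waveforms are invariant under noise-level changes.

Trials are 4 s; with 1-s non-overlapping windows the 128 trials yield
512 windows, of which a stratified 400 train / 100 test split is used. The desk-scale
model (`desk_model_config()`: T = 4, L = 2, d = 32, 4 × 4 tokens, 8 heads,
32 × 32 maps) trains for 30 epochs with Adam at lr 1e-3 and batch 16.
The desk learning rate differs from the full-scale default (1e-4) because
30 short epochs move Adam only ~0.04 in parameter space at 1e-4; 1e-3 is
the standard small-budget Adam choice. A 4 × 4 token grid (rather than
8 × 8) is the package's desk-scale choice: 32 × 32 maps of smooth
alpha-power fields are heavily oversampled, sixteen tokens retain the
lateralization signal, and the wavelet filter — the model's dominant
cost — scales with the token count, keeping the ten-training ablation
experiment tractable on one CPU core.

What passing this experiment shows: the full pipeline — filtering,
topographic encoding, surrogate-gradient optimization through binary
activations, and the fused wavelet-attention block — can extract a known
spatial-spectral class structure end-to-end. What it does not show:
performance on real EEG. The generator has no volume-conduction forward
model, no eye or muscle artifacts, no inter-subject variability, and its
class signal is stronger and cleaner than real attention or emotion
correlates; published benchmark accuracies are not reproducible from it.

## Numerical choices and degenerate inputs

* Chebyshev type II filters are specified by stopband edges; these are
  placed *outside* the requested passband (at half the low edge and 1.5×
  the high edge for the main filter) so in-band tones pass at unity gain.
  Stopband attenuation defaults to 40 dB, doubled by the forward-backward
  pass.
* `signal::resample`'s polyphase path carries an uncompensated group
  delay, so resampling is implemented as zero-phase low-pass filtering at
  90% of the target Nyquist plus spline evaluation on the new sample
  grid.
* Max-pooling over binary spikes has ties everywhere; the gradient routes
  to the first maximum in a fixed scan order, making training
  deterministic.
* Prediction ties break toward the lower class index; constant channels
  inside a trial abort standardization with the channel and trial named;
  windows longer than their trial produce zero windows and a warning.
* The gradient checker runs the network in a *relaxed* mode in which the
  spike function becomes the sharpened sigmoid in the forward pass and
  the reset is differentiated exactly; the relaxed network is smooth, so
  finite differences probe exactly what the backward pass computes. The
  spiking-mode backward shares all code except the spike derivative.
* Problem sizes in the test suite: the isometry sweep uses 1,000 random
  map pairs up to 64 × 64; the LIF oracle comparison uses 10,000 random
  sequences of 50 steps; the learning experiment uses the fixed 400/100
  split with five seeds per arm.

## Known limitations

* Multi-level wavelet decompositions and non-Haar bases are out of scope
  (the Haar basis is the method's stated choice).
* EDF and HDF5 I/O are not provided; the container is RDS plus a CSV/JSON
  plain-text export.
* The energy model abstracts per-operation costs; it is not a
  hardware-level (joule) estimate.
* Training is single-threaded CPU; there is no GPU path and no
  distributed training.
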