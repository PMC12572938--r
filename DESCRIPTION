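Package: spikewavformer
Title: Spiking Wavelet Transformer for EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end spiking transformer for multi-channel EEG
    classification that fuses spiking self-attention with a single-level
    orthonormal 2D Haar wavelet branch. Provides leaky integrate-and-fire
    (LIF) neuron dynamics with sigmoid surrogate-gradient training, an EEG
    preprocessing front end (average re-reference, Chebyshev type II
    band-pass, resampling, per-trial standardization, sliding decision
    windows), alpha-band topographic-map encoding, a synthetic EEG generator
    with controllable hemispheric alpha asymmetry for fully reproducible
    desk-scale experiments, and a spike-rate based energy-consumption
    estimator comparing the spiking network against its conventional
    artificial-neural-network counterpart.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    withr
Config/testthat/edition: 3
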