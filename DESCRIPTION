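Package: graspwave
Title: Wavelet-Feature Decoding of Hand-Grasp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for decoding hand-grasp type (power grasp,
    precision grasp, no movement) from multichannel EEG epochs. Implements
    complex Morlet wavelet time-frequency decomposition, statistical
    wavelet-amplitude features per channel and frequency band, stratified
    cross-validated classification with four model families, and permutation
    feature importance with topographic scalp mapping. Includes a synthetic
    EEG generator (1/f background plus class-dependent oscillatory bursts
    over motor channels) with ground-truth effect placement for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    ranger,
    xgboost,
    MASS,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
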