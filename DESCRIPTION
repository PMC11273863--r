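Package: pigvoc
Title: Pig Vocalization Detection from Farm Audio with Fused Spectral
    Features and a Compact Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying 3-second farm audio clips into pig
    vocalization versus non-vocalization. Provides WAV input/output and
    preprocessing (mono conversion, resampling to 22,050 Hz, 3-second
    segmentation, dBFS measurement), four spectral feature extractors
    (20-band MFCC, 128-band log-Mel spectrogram, 12-class chroma,
    6-dimensional tonal centroids) and their 166-row fused
    representation, a four-operator audio augmentation recipe
    (pitch-shift, time-shift, time-stretch, background noise), a fixed
    three-block convolutional network with closed-form parameter and
    FLOP counters, stratified fivefold cross-validation, and a
    leave-one-farm-out robustness protocol. A seeded synthetic "virtual
    farm" generator produces balanced two-class datasets with
    farm-specific noise character and loudness so the whole pipeline is
    testable without access to private farm recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'rng.R'
    'audio-io.R'
    'stft.R'
    'synth.R'
    'features.R'
    'augment.R'
    'dcnn.R'
    'train.R'
    'eval.R'
    'pigvoc-package.R'
    'RcppExports.R'
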