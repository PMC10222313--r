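Package: emgimage
Title: Signal-to-Image Encoding and Convolutional Classification of
    Multi-Channel Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for hand-gesture recognition from
    multi-channel surface electromyography (sEMG): synthetic armband-style
    sEMG simulation, powerline notch and DC-block preprocessing,
    sliding-window segmentation, three signal-to-image encoders
    (time-domain images, stacked short-time Fourier spectrograms, and
    feature-enhanced spectrograms with a pointwise-maximum auxiliary
    channel), two small convolutional neural networks implemented in
    'RcppArmadillo', and an evaluation harness that compares encoders and
    channel counts with confusion matrices and per-class accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
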