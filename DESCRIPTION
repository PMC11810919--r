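Package: gbseg
Title: Gallbladder CT Segmentation with Multi-Scale Channel Attention U-Nets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Builds, trains and evaluates encoder-decoder networks for
    gallbladder segmentation on abdominal CT slices: a pinned baseline U-Net,
    SEU-Net with squeeze-and-excitation channel attention, and MCAU-Net with
    multi-scale channel attention blocks in the encoder. Includes the CT slice
    preparation chain (Hounsfield conversion, window/level adjustment,
    contrast-limited adaptive histogram equalization, normalization),
    patient-grouped dataset splitting with geometric augmentation, Dice and
    binary cross-entropy training losses, a seven-metric segmentation
    evaluation suite with cohort aggregation, and a seeded synthetic
    gallbladder-phantom generator emulating the extreme class imbalance of
    clinical data. The network engine (trainable convolutions, reverse-mode
    differentiation, Adam) is implemented natively on Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    png,
    RNifti,
    EBImage,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
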