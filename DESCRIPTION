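Package: alcoeeg
Title: Wavelet-Denoised Deep Learning Classification of Alcoholic EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for binary classification of alcoholic
    versus control EEG trials. Provides a reader for the UCI SMNI plain-text
    trial format, per-feature standardization, a from-scratch multilevel
    discrete wavelet transform used as an approximation-cascade denoiser, a
    one-dimensional CNN plus bidirectional-LSTM classifier with reference
    LSTM-cell kernels, baseline architectures (CNN, LSTM, Bi-LSTM,
    CNN+Bi-LSTM), confusion-matrix evaluation metrics, and a seeded
    synthetic-EEG generator so the whole pipeline is testable without any
    external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
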