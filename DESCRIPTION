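Package: cardiomel
Title: Heart Sound Classification with Improved Mel-Frequency Cepstral Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for three-class phonocardiogram (PCG) classification
    into normal, abnormal and noise recordings. Provides zero-phase Butterworth
    low-pass preprocessing, down-sampling and fixed-length segmentation of heart
    sound audio; an improved mel-frequency cepstral coefficient (MFCC) feature
    extractor that stacks static cepstra with first- and second-order difference
    coefficients into a 199 x 39 feature matrix per 2-second segment; a small
    neural-network engine with declarative builders for residual convolutional,
    LSTM, GRU and plain CNN architectures with exact parameter counting; a
    grouped, stratified five-fold evaluation protocol with class balancing and
    confusion-matrix metrics; and a seeded synthetic phonocardiogram generator
    so the full pipeline is testable without any external corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
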