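Package: lcmcs
Title: Soil Total Nitrogen Prediction from Vis-NIR Spectra by Local
    Correlation Maximization and Complementary Superiority
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric calibration of soil total nitrogen (TN) from
    visible/near-infrared reflectance spectra (350-2500 nm). Implements
    spectral transforms (first derivative, reciprocal logarithm), per-band
    wavelet local-correlation-maximization denoising (LCM) with sym8
    multilevel decomposition, correlation-based effective-band selection,
    NIPALS partial least squares, and a Takagi-Sugeno adaptive neuro-fuzzy
    inference system (ANFIS) trained by hybrid least-squares/gradient
    learning, combined into the LCMCS pipeline and its PLS, LCM and CS
    comparison pipelines, with calibration/validation reporting and a
    synthetic soil-spectra generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
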