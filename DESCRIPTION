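Package: fgrs
Title: Fluorescence-Guided Raman Spectroscopy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fluorescence-guided Raman spectroscopy
    (FGRS) of single cells: asymmetric-least-squares baseline correction of
    the fingerprint region, cosmic-ray spike rejection against the Amide I
    reference intensity, maximum-intensity normalization, topographic
    peak-prominence analysis, band-wise rank-sum tests and pooled-SD Cohen's
    d effect sizes, double-standard-deviation wavenumber selection, and
    Gaussian-kernel support vector machine classification of cells with high
    versus low Connexin 43 content. Includes a calibrated synthetic spectrum
    generator (pseudo-Voigt bands, fluorescence backgrounds, cosmic rays)
    that programs band effect sizes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
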