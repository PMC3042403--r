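Package: drspectra
Title: Tissue Differentiation from Diffuse Reflectance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying tissue types from visible-range
    diffuse reflectance spectra. Converts raw spectrometer counts to percent
    reflectance against a lamp reference and dark background, restricts
    spectra to the informative 350-650 nm window, standardizes wavelength-wise,
    reduces dimension by principal component analysis with Mann-Whitney
    U-test based selection of discriminative components, and classifies with
    multiclass linear discriminant analysis posteriors. Performance is
    evaluated by specimen-grouped leave-one-out cross-validation and pairwise
    ROC analysis with Youden-optimal cutpoints. Includes a hierarchical
    synthetic spectra generator (specimen, spot and repeat levels, hemoglobin
    absorption bands, wavelength-dependent detector noise) so the full
    pipeline can be exercised and calibrated without access to measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
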