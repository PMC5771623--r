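Package: lncspec
Title: Leaf Nitrogen Estimation from Reflectance and Laser-Induced
    Fluorescence Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating leaf nitrogen content (LNC) of paddy rice
    from paired leaf spectra: a registry of 67 published reflectance
    vegetation indices, seven laser-induced chlorophyll fluorescence
    ratio parameters, wavelet denoising of spectra, support-vector
    regression with the ANOVA kernel under k-fold cross-validation, and a
    synthetic paired-spectra generator with nitrogen-linked pigment and
    fluorescence structure for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
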