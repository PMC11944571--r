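Package: chlorospec
Title: Chlorophyll Calibration from Vis/NIR Leaf Spectra with
    Representative Subset Selection
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating leaf chlorophyll content from
    visible/near-infrared reflectance spectra. Implements the full
    calibration workflow: conversion of reflectance to absorbance and
    Savitzky-Golay smoothing, Kennard-Stone selection of calibration
    samples, a mean-squared-distance (MSD) statistic that compares
    Gaussian kernel density estimates of principal-component scores to
    judge how well a candidate subset represents a validation
    population, partial least squares regression with
    leave-one-out-selected latent variables and VIP band analysis, and
    a Cubist-style rule-based regression model (model trees, residual
    committees, nearest-neighbour correction). A synthetic leaf-spectra
    generator reproduces the statistical structure of a multi-species,
    multi-month field campaign so that every stage can be exercised and
    tested without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    mixOmics
Config/testthat/edition: 3
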