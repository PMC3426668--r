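Package: cgmr
Title: Cardiogoniometry Signal Processing and Diagnostic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the cardiogoniometry (CGM) analysis chain: conversion
    of five-lead thoracic potential recordings into an orthogonal 3D heart-vector
    trajectory, beat detection and segmentation into P, R (QRS) and T loops,
    median-loop averaging, extraction of angle, amplitude, shape, octant,
    velocity and variability parameters, and classification by an out-of-range
    penalty score against stratified reference ranges calibrated from controls.
    Ships a ground-truthed synthetic vectorcardiogram generator with
    ischaemia-like perturbations, a synthetic diagnostic-cohort generator with
    specified test operating characteristics and latent-severity dependence,
    and the paired diagnostic-accuracy toolkit (2x2 metrics with exact
    fractions, McNemar tests, chi-square/Fisher selection, OR-combination of
    tests, and screening-yield NNT/NNH).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
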