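Package: limbrqa
Title: Multidimensional Recurrence Quantification Analysis of Four-Limb
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the complexity of multi-limb movement from
    wearable accelerometer recordings. Simulates four-limb 3-axis
    acceleration sessions with rhythmic or unstructured dynamics and
    longitudinal cohort designs; preprocesses raw traces (cubic-spline gap
    interpolation, acceleration magnitude, third-order median filter,
    z-scoring); estimates phase-space embedding parameters (average mutual
    information delay, false-nearest-neighbour dimension, radius calibrated
    to a fixed recurrence rate); computes multidimensional recurrence
    quantification measures (recurrence rate, diagonal-line entropy, mean
    line) with a streaming per-diagonal kernel; runs shuffled-surrogate
    controls with paired t-tests; and fits marginal (GEE) task-by-age
    repeated-measures models with exchangeable working correlation, robust
    standard errors, Wald term tests and Bonferroni-corrected pairwise
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
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
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
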