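Package: gaitwomac
Title: Gait-Cycle Feature Analysis and Estimation of WOMAC Knee-Osteoarthritis Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the relationship between instrumented gait
    analysis and patient-reported knee-osteoarthritis severity measured by the
    WOMAC index. Provides WOMAC scoring and mild/moderate/severe
    classification, gait-cycle normalisation and sub-phase segmentation, a
    large registry of waveform feature operators (summary statistics, areas
    under the curve, phase extrema, power-spectral-density and occupied
    bandwidth, autocorrelation bounds, mid-reference level, and dynamic time
    warping between stance and swing), ANOVA plus Bonferroni-corrected
    pairwise t-test feature selection, linear and random-forest regression of
    WOMAC totals under class-balanced hold-out validation, a synthetic cohort
    generator with planted severity effects for end-to-end validation, and a
    CSV-based pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
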