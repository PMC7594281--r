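Package: lipomics
Title: MRI Radiomics Pipeline for Lipomatous Soft-Tissue Tumor Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts an 87-feature radiome (size, shape, intensity
    distribution, gray-level co-occurrence / run-length / size-zone /
    neighborhood gray-tone difference textures, and Gabor filter-bank
    statistics) from a 2D tumor slice with a binary mask, using
    equal-probability gray-level discretization averaged over seven level
    counts. Provides inter-observer reproducibility statistics,
    gray-level-discretization stability (coefficient of variation) analysis,
    dual-criterion feature filtering (t-test relevancy and Pearson
    reproducibility), a linear support-vector classifier trained by
    sequential minimal optimization with stratified holdout evaluation, and
    a synthetic two-class tumor phantom generator so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    data.table,
    RNifti,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab,
    withr
Config/testthat/edition: 3
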