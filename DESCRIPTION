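Package: proteoclock
Title: Plasma Proteomic Aging Clocks by Penalized Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build and evaluate plasma proteomic aging clocks: simulate
    SOMAscan-like cohorts with known age structure, score per-analyte age
    associations with false-discovery-rate control, fit ridge and LASSO age
    predictors on z-scaled log10 intensities with tenfold cross-validation
    over a 100-value lambda path, screen pathway-restricted clocks, transfer
    clocks across measurement panels with a slope-offset correction, compare
    group delta ages, and test pathway overrepresentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
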