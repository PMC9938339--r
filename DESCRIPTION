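Package: survalid
Title: External Validation of Proportional-Hazards Risk Prediction Models
    Under Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating published proportional-hazards
    risk prediction models (prognostic-index scoring from declarative model
    definitions, outcome-fraction scaling for composite tools) against
    time-to-event cohorts with competing risks. Implements Harrell's C-index
    with a competing-risk adaptation, calibration slope via a single-covariate
    Cox fit, mean and decile-based calibration against Kaplan-Meier or
    Aalen-Johansen cumulative-incidence references, censoring-adjusted
    sensitivity and specificity at observed-risk and clinical thresholds, and
    a synthetic older-cohort generator with known ground truth for end-to-end
    testing of the validation pipeline.
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
    Rcpp,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
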