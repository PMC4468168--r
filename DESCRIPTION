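Package: thermotol
Title: Randomization Tests and Thermal Performance Curves for Insect
    Thermal-Tolerance Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for cold- and heat-tolerance assay data in
    ectotherms, built around difference-in-medians randomization tests,
    percentile bootstrap confidence intervals for group medians, and
    quasi-binomial cubic logistic models of egg-to-adult viability across
    developmental temperatures with benign-temperature standardization.
    Includes calibrated synthetic-data generators (skewed tolerance scores,
    overdispersed beta-binomial vial counts, microhabitat temperature logs)
    so the full pipeline runs and is testable without field data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
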