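Package: fqad
Title: Comparative Cohort Analysis of Antibiotic-Associated Disability in
    Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a new-user, active-comparator cohort analysis of
    antibiotic-associated disability (adverse events in two or more system
    organ classes together with an incident short-term disability claim) in
    administrative claims data. Implements cohort construction with
    indication, eligibility and exclusion logic, claims-based outcome
    phenotyping with diagnosis confirmation windows, LASSO propensity-score
    estimation with trimming and 1:1 greedy caliper matching, matched-pair
    conditional odds ratios, and negative-control-based empirical p-value
    calibration. Ships a synthetic claims generator with known ground truth
    so every pipeline stage is testable without licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    glmnet,
    Matrix,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
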