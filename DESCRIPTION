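Package: dynmeld
Title: Revising MELD-Type Liver Allocation Scores from Calendar-Time
    Cross-Sections with Inverse Probability of Censoring Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to revise Model for End-stage Liver Disease (MELD)
    style waitlist mortality scores from a longitudinal transplant
    waitlist registry.  Builds 90-day time-stopped analysis datasets
    either from registration or from pre-specified calendar-time
    cross-sections, corrects for dependent censoring by transplantation
    and delisting with inverse probability of censoring weights
    (IPCW-T and IPCW-D), fits weighted stratified Cox proportional
    hazards models with optional score offsets, optimizes biomarker
    caps by profile log-likelihood, rescales fitted coefficients to the
    MELD point scale by quantile matching, and validates candidate
    scores with a time-truncated concordance index corrected for
    dependent censoring, cluster-bootstrap score comparisons and
    absolute 90-day risk tables.  A synthetic registry generator with
    severity-driven biomarker reporting and biomarker-dependent
    transplant and delisting hazards provides ground-truth scenarios
    for parameter-recovery and bias studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival (>= 3.4),
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
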