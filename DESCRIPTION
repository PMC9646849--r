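Package: iecval
Title: Interchangeability Validation of Automated Versus Multi-Reader
    Measurements via the Individual Equivalence Coefficient
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical framework for deciding whether an automated
    measurement source (for example a deep-learning echocardiography
    workflow) is interchangeable with a panel of three human expert
    readers.  Implements the individual equivalence coefficient (IEC)
    with bootstrap non-inferiority testing against a prespecified
    margin, per-parameter measurement yield with binomial quantile
    intervals, a battery of secondary agreement metrics (two-way
    random-effects ICC, mean absolute pairwise deviation, within-patient
    coefficient of variation, two-way residual RMSE, Lin's concordance
    correlation, Bland-Altman limits of agreement, coverage
    probability, relative absolute differences), Monte-Carlo power and
    sample-size simulation, and a seeded synthetic multi-reader data
    generator with a confidence-gated missingness mechanism so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
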