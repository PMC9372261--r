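Package: modmod
Title: Moderated Moderation Analysis with Slope-Difference Tests and
    Monte Carlo Power
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for probing three-way (moderated moderation) interactions
    in ordinary least squares regression, built around a depression screening
    workflow for questionnaire cohorts. Scores the PHQ-9, the SCL-90
    interpersonal-sensitivity subscale, the PCQ-24 psychological capital
    questionnaire and a 20-item binary family-support scale with Cronbach's
    alpha and KR-21 reliability; applies data-quality exclusion rules, a
    PHQ-9 >= 5 screen, descriptive and correlation summaries, pooled t-tests
    and Harman's single-factor test; fits standardized two-way and three-way
    interaction models with full inference from first principles; computes
    simple slopes at +/-1 SD of both moderators and all pairwise
    slope-difference contrasts with covariance-based z tests; estimates
    moderation power by Monte Carlo simulation; and generates synthetic
    item-level cohorts with configurable correlation structure, regression
    structure and contamination so the whole pipeline is testable without
    raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
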