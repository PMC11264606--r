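Package: prefcross
Title: Scoring, Agreement and Crosswalking of Preference-Based Health Utilities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparing the EQ-5D-5L and PROMIS-based (PROPr)
    preference scores: configurable value-set scoring engines for both
    instruments, agreement statistics (product-moment correlation, two-way
    mixed- and random-effects intraclass correlations from the ANOVA mean
    squares, normalized mean absolute error, Cohen d-to-r conversion), a
    bidirectional OLS crosswalk with linear equating and range clamping
    (including the published U.S. general-population mapping constants), a
    beta-regression alternative on the unit interval, condition-indicator
    regression comparison, back-pain instrument scoring (ODI, RMDQ, PEG,
    STarT Back, GCPS), and a moment-calibrated synthetic cohort generator
    with a ceiling-censored utility mechanism so the full analysis pipeline
    can be exercised without person-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmmTMB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
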