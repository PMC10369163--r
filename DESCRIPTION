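Package: lcsmediate
Title: Latent Change Score Models, Longitudinal Mediation, and Clinical
    Significance for Two-Arm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing two-arm randomized trials with repeated
    sum-score outcomes: fixed-loading latent change score (difference score)
    regression systems with maximum-likelihood or least-squares standard
    errors and an EM-based full-information option for incomplete data;
    single- and multi-mediator change-score mediation with bias-corrected
    bootstrap confidence intervals for indirect effects; questionnaire
    scoring, severity banding, and Cronbach's alpha for standard depression
    and mechanism instruments; Jacobson-Truax clinical-significance indices
    (high-end-state functioning, reliable change index) and Cohen's d; and a
    synthetic-trial generator with stratified permuted-block randomization,
    wave-specific attrition, and message-level engagement streams for fully
    reproducible testing of every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
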