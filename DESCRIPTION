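Package: vstraj
Title: Vital-Sign Trajectory Subphenotyping for Suspected Infection
Version: 0.1.0
Authors@R: person("vstraj", "maintainers", email = "vstraj@example.org",
    role = c("aut", "cre"))
Description: Group-based trajectory modelling (GBTM) of five vital-sign
    channels (temperature, heart rate, respiratory rate, systolic and
    diastolic blood pressure) over the first 24 hours of emergency-department
    admission in patients with suspected infection. Provides a finite-mixture
    EM fitter with polynomial group trajectories, BIC-based selection over 1-4
    groups with minimum-share and posterior-adequacy screens, clinical A-D
    subphenotype labelling, and the downstream 30-day mortality association
    stage (contingency odds ratios with Woolf intervals, unconditional
    logistic regression, chi-square and likelihood-ratio tests with the
    expected-count rule, tie-corrected ROC AUC with Hanley-McNeil standard
    errors, and one-way ANOVA with Bonferroni correction), together with a
    fully synthetic emergency-department cohort generator and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
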