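Package: mrmediate
Title: Bidirectional Mendelian Randomization, Cox Modelling and Mediation for a Survival Outcome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A causal-inference toolchain for adiposity-biomarker-disease
    questions: two-sample Mendelian randomization on harmonized GWAS
    summary statistics (fixed-effect inverse-variance weighted, weighted
    median with parametric-bootstrap standard errors, and MR-PRESSO
    outlier detection), instrument quality control (F-statistics,
    genome-wide significance and pleiotropy exclusion lists), Cox
    proportional-hazards association modelling in a prospective cohort
    (nested covariate models, per-SD and quartile codings, first-year
    sensitivity analysis, proportional-hazards checks), and counterfactual
    mediation for a rare survival outcome (natural direct and indirect
    effects on the log hazard-ratio scale, proportion mediated, delta-method
    and bootstrap confidence intervals). Includes seed-deterministic
    generators for GWAS summary tables and cohort survival data with known
    ground truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
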