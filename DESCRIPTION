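Package: steroidiag
Title: Steroidomic Diagnostic Models for Alzheimer's Disease and Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for serum steroidome-based diagnostics of
    Alzheimer's disease (AD) and type 2 diabetes mellitus (T2DM). Implements
    per-variable Box-Cox power transformation to near-normality with
    back-transformed ("retransformed") summaries, age-adjusted two-factor
    ANCOVA (AD, T2DM, interaction) with Bonferroni pairwise comparisons,
    orthogonal projections to latent structures (OPLS) binary discriminant
    models with variable-importance (VIP) predictor pruning, Hotelling T2
    outlier screening, seven-fold cross-validation, likelihood-ratio
    probability calibration, and sensitivity/specificity reporting with
    unclipped Wald intervals. Ships a synthetic-cohort generator calibrated
    to published per-group retransformed means, confidence intervals and
    class-axis component loadings, so the full pipeline is testable without
    access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    car,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
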