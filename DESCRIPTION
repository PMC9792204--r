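Package: grimage2
Title: DNA Methylation GrimAge2 Mortality Clocks and Surrogate Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and validation of second-generation DNA methylation
    (DNAm) mortality clocks. Implements the two-stage GrimAge2 procedure:
    Stage 1 trains elastic-net DNAm surrogates of winsorized, log-transformed
    plasma analytes (e.g. C-reactive protein, hemoglobin A1C) from CpG beta
    values plus age and sex; Stage 2 fits an elastic-net Cox model of
    all-cause mortality on the surrogates and calibrates its linear predictor
    to units of years by mean/variance matching against chronological age.
    Ships the published 12-covariate GrimAge2 coefficient model, age
    acceleration residuals, Cox deviance-residual mortality scores, and the
    validation battery used for epigenetic clocks: biweight midcorrelation,
    inverse-variance fixed-effect and Stouffer meta-analysis, cluster-robust
    Cox and logistic associations, and per-CpG EWAS screens with six-SD
    outlier masking. A synthetic cohort generator with known ground truth
    supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
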