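Package: diastolr
Title: Diastolic Function Phenotyping, Genetic Association and Mendelian
    Randomization on Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving diastolic function traits (peak early
    diastolic strain rates and body-surface-area-indexed maximal left
    atrial volume) from cardiac cine geometry, and for studying their
    genetic architecture on simulated cohorts with known ground truth:
    variant quality control, covariate-adjusted association scans,
    greedy linkage-disequilibrium clumping, LD-score regression for
    heritability and genetic correlation, gene-level loss-of-function
    burden tests, polygenic instrumental variable scores with
    phenome-wide scans and leave-one-SNP-out sensitivity analysis, and
    bidirectional two-sample Mendelian randomization (inverse-variance
    weighted, weighted median, MR-Egger and an MR-PRESSO-style outlier
    test) with a reproducible causal decision rule. A seeded synthetic
    data generator emulates block-correlated genotypes, polygenic traits
    with covariate effects, liability-threshold disease endpoints and
    per-subject cine geometry, so every stage of the pipeline can be
    validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
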