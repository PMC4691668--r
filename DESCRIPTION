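Package: hcymr
Title: Mendelian Randomization Analysis of Homocysteine and Blood Pressure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-sample and two-sample Mendelian randomization estimators for
    the causal effect of circulating homocysteine on systolic and diastolic
    blood pressure. Implements ordinary least-squares and two-stage
    least-squares regression with first-stage instrument diagnostics and the
    Durbin-Wu-Hausman endogeneity test on individual-level cohort data;
    effect-allele harmonization, fixed-effects meta-analysis with Cochran's Q
    and I-squared, single- and multi-SNP inverse-variance-weighted estimation,
    and MR-Egger pleiotropy regression with percentile-bootstrap confidence
    intervals on GWAS summary statistics. Includes seeded generators for
    synthetic birth-cohort tables and 18-SNP summary panels so that every
    estimator is verifiable by parameter recovery, and a pipeline that runs
    the full analysis plan and renders machine-readable results and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    nnet,
    jsonlite,
    yaml,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
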