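Package: osteomr
Title: GWAS Meta-Analysis, LD Score Regression and Two-Sample Mendelian
    Randomisation for Fracture Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for dissecting the genetic and clinical
    determinants of osteoporotic fracture risk: fixed-effects inverse-variance
    meta-analysis of case-control GWAS summary statistics with per-study
    genomic control, allele harmonisation of exposure/outcome summary
    statistics, greedy linkage-disequilibrium clumping of instruments, a
    two-sample Mendelian randomisation estimator suite (Wald ratio,
    inverse-variance weighted, MR-Egger, weighted and penalised weighted
    medians) with power calculation and Bonferroni flagging, LD score
    regression for heritability and genetic correlation with block-jackknife
    errors, and seeded synthetic-data generators that produce multi-cohort
    case-control GWAS output, two-sample instrument sets with configurable
    pleiotropy, and polygenic z-score pairs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
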