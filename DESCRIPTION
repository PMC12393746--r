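Package: lipidratio
Title: Lipid-Ratio Phenotypes, p-Gain Association and Mixed-Model GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for systems-genomics analysis of plasma lipidomics data
    with pathway-informed lipid ratios. Constructs class sums and
    standardized log2 ratio phenotypes from lipid concentration tables,
    harmonizes cohorts with reference-plasma, matched sub-cohort and pooled
    quality-control corrections, tests covariate-adjusted associations with
    obesity markers including the p-gain statistic and sex-interaction
    models, performs correlation-adjusted lipid-set enrichment with a
    chi-squared null, and runs an EMMAX-style linear mixed-model GWAS on
    ratio phenotypes with leave-one-chromosome-out kinship. A synthetic
    two-cohort lipidome and genotype generator makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
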