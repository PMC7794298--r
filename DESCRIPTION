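Package: sumshare
Title: Lossless Distributed Score Test for Pleiotropy Across Multiple Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pleiotropy of a single SNP across multiple binary
    phenotypes using only summary-level statistics exchanged between
    clinical sites and a central analyst. Implements a composite-likelihood
    score test whose distributed two-round computation is mathematically
    identical to analysing the pooled individual-level data, with stratified
    adjustment for categorical covariates. Includes per-phenotype logistic
    regression PheWAS baselines (inverse-variance-weighted meta-analysis and
    pooled mega-analysis), a synthetic multi-site data generator for
    correlated binary phenotypes under Hardy-Weinberg genotypes, and a
    Monte-Carlo harness for power, type-I error and losslessness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
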