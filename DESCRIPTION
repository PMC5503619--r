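Package: subtypenmf
Title: NMF Consensus Molecular Subtyping of Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene expression-based molecular subtyping of tumor cohorts:
    quantile normalization, an integrated permutation-calibrated
    differential-expression statistic (Welch t and log2-median-ratio tests
    combined by Stouffer's method), nonnegative matrix factorization (NMF)
    consensus clustering with cophenetic-coefficient rank selection,
    subtype-specific marker selection, cross-classification concordance
    against external subtype labels, clinicopathologic association tests,
    and Kaplan-Meier/log-rank survival analysis, together with a synthetic
    cohort generator with planted subtypes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    limma,
    matrixStats,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
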