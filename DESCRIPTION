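Package: mrlab
Title: Two-Sample Mendelian Randomization and Cross-Trait Genetic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable toolkit for causal inference and shared-genetics analysis
    from GWAS summary statistics. Implements harmonization of two-sample summary
    statistics (palindrome exclusion, allele alignment), greedy LD clumping and
    instrument selection with strength diagnostics (instrument F statistic,
    variance explained), a battery of two-sample Mendelian randomization
    estimators (multiplicative random-effects IVW, weighted median, Egger
    regression, robust adjusted profile score, pleiotropy residual sum and
    outlier test, Steiger directionality, leave-one-out), two-step MR mediation
    decomposition by the product of coefficients, cross-phenotype meta-analysis
    (subset-maximized heterogeneous statistic), LD-score-regression genetic
    correlation with block-jackknife errors, colocalization posterior
    probabilities from approximate Bayes factors, a TWAS weighted-burden
    association statistic, analytic power for binary-outcome MR, and a
    block-LD synthetic GWAS generator with controlled heritability, genetic
    correlation and mediation structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
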