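Package: summarymr
Title: Two-Sample Mendelian Randomization, Mediation and Colocalization
    from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained two-sample Mendelian randomization (MR)
    toolkit for GWAS summary statistics: reading, validation and
    allele harmonization of per-variant association tables; instrument
    screening at multiple genome-wide significance levels with greedy
    linkage-disequilibrium clumping; univariable causal-effect
    estimation by the Wald ratio (single instrument) and
    inverse-variance-weighted (IVW) estimators with Cochran Q
    heterogeneity and MR-Egger intercept pleiotropy diagnostics;
    bi-directional mediation MR with the product-of-coefficients
    proportion mediated; multivariable MR for direct effects;
    approximate-Bayes-factor colocalization over two-trait regions;
    and a synthetic summary-statistics generator with known causal
    architecture so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
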