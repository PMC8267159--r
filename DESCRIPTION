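Package: mratlas
Title: Two-Sample Mendelian Randomization Atlas Toolkit
Version: 0.1.0
Authors@R: person("Atlas", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for building phenome-scale causal atlases with two-sample
    Mendelian randomization from GWAS summary statistics. Provides instrument
    selection at genome-wide significance, greedy LD clumping, allele
    harmonization with palindromic-variant resolution, the Wald ratio,
    inverse-variance weighted, MR-Egger and weighted-median causal estimators
    with instrument-count dispatch, a sensitivity battery (single-SNP,
    leave-one-out, Egger intercept, funnel data, Cochran's Q, and the
    MR-PRESSO global, outlier and distortion tests), instrument-strength and
    power diagnostics for binary outcomes, Bonferroni tiering across a trait
    panel, bidirectional-MR network construction among significant traits, and
    a seeded synthetic GWAS summary-statistics generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
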