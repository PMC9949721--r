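Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) workflow for
    GWAS summary statistics: instrument filtering (significance, minor allele
    frequency, imputation quality, confounder exclusion) with per-instrument
    and overall F-statistics, effect-allele harmonization with palindromic-SNP
    handling and LD-proxy substitution, causal-effect estimation by Wald
    ratios, inverse-variance weighting (fixed or multiplicative random
    effects), MR-Egger regression and the weighted median, Cochran's Q
    heterogeneity and Egger-intercept pleiotropy diagnostics, MR-PRESSO
    global/outlier/distortion tests with outlier-corrected estimates,
    leave-one-out sensitivity analysis, Bonferroni adjustment across outcomes,
    and binary-outcome statistical power. Includes a seeded generator of
    synthetic two-sample GWAS summary tables with known causal effect and
    pleiotropy structure for calibration and recovery studies, and a pipeline
    driver that runs the full analysis from a declarative configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
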