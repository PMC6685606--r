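Package: mrsum
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A summary-statistic Mendelian randomization toolkit: ingestion and
    allele harmonization of two-sample GWAS summary data, greedy LD clumping
    and instrument-strength metrics (R-squared, F-statistic), the Wald-ratio
    estimator suite (inverse-variance-weighted fixed and multiplicative
    random effects, MR-Egger, weighted median, weighted mode), sensitivity
    diagnostics (Cochran's Q, leave-one-out, Steiger directionality),
    liability scaling for binary exposures, Bonferroni evidence tiers, and a
    generator of synthetic two-sample summary statistics with known causal
    and pleiotropic structure for method validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    readxl,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
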