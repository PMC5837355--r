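Package: depotmr
Title: Two-Sample Mendelian Randomization of Fat Distribution on Adiponectin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for two-sample Mendelian randomization
    (MR) from GWAS summary statistics, built around the analysis of abdominal
    (waist circumference) and gluteofemoral (hip circumference) fat
    distribution as causal determinants of circulating adiponectin. Provides
    reading and allele harmonization of summary-association tables, instrument
    selection (genome-wide significance filtering, greedy LD pruning,
    cross-trait overlap exclusion), variance-explained and power calculations,
    causal estimation by inverse-variance weighted (IVW), multivariable IVW,
    MR-Egger, and (penalized) weighted-median methods with bootstrap
    confidence intervals, heterogeneity and pleiotropy diagnostics (Cochran's
    Q, I-squared with confidence interval, funnel asymmetry, heterogeneous
    variant removal), fractional-polynomial dose-response testing for cohort
    data, and a synthetic-data generator that emulates consortium-scale
    summary statistics and a birth-cohort body-composition study so the whole
    pipeline can be exercised offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
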