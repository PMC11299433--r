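Package: mrmediate
Title: Two-Sample Mendelian Randomization and Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics and for two-step MR mediation analysis. Covers
    instrument selection (significance thresholding, greedy clumping,
    F-statistic filtering), allele harmonization, the standard causal
    estimators (Wald ratio, fixed- and random-effects inverse-variance
    weighted, MR-Egger, weighted median), a sensitivity suite (Cochran's Q,
    Egger intercept, leave-one-out, MR-PRESSO outlier detection, Steiger
    directionality), and mediated-proportion estimation with delta-method
    confidence intervals. Includes a summary-statistics simulator with
    configurable pleiotropy and mediation structure so the full pipeline is
    testable without external data, plus tidy and ggplot2-based diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
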