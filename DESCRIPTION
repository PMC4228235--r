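Package: chargenes
Title: Characteristic Developmental Genes and Gene-Set Over-Representation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies characteristic genes of a developing-organ expression
    time series from the loading-coefficient magnitudes of a principal
    component analysis of samples in gene space, and tests curated gene sets
    for over-representation among them and among paired Wilcoxon signed-rank
    differential-expression results. Includes probe-to-gene collapse rules
    (maximum replicate-profile correlation; minimum signed-rank p), per-sample
    standardization, local-regression smoothing of age profiles, two-sided
    Fisher exact overlap tests with sample and conditional-maximum-likelihood
    odds ratios and conditional 95 percent confidence intervals (Cornfield
    continuity-corrected and exact tail-inversion), and seeded simulators for
    replicated developmental series and paired two-condition cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
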