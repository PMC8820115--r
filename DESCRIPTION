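Package: pecklat
Title: Visual Lateralization Analysis for Avian Feeding Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing eye-use lateralization in foraging birds from
    tabular peck-event records. Classifies individual eye preference with exact
    and continuity-corrected binomial tests, computes laterality indices and
    population-level nonparametric statistics (one-sample Wilcoxon signed rank,
    Mann-Whitney, Kruskal-Wallis with tie correction, Cohen's kappa for
    inter-rater agreement), analyses eye-conditional feeding accuracy under a
    balanced fixed-error design, compares feeding efficiency between groups,
    and tests for pseudoreplication bias with a Monte-Carlo synthetic-flock
    resampling null. Includes a configurable synthetic peck-event generator
    for calibration and power studies.
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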