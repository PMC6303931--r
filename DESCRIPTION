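Package: chronocope
Title: Circadian Rhythmicity and Coping-Style Analysis for Zebrafish Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how circadian rhythmicity co-varies with
    animal personality along the proactive-reactive continuum. Generates
    seeded synthetic zebrafish cohorts in which clock-gene expression,
    cortisol and melatonin secretion and locomotor activity are rhythmic
    channels whose amplitude declines from bold (early-emerging) to shy
    (late-emerging) individuals; quantifies rhythmicity with LOWESS
    smoothing, fixed-period 24-hour sinusoid fits, area under the curve,
    rhythm strength and maximum swimming velocity; scores emergence and
    mirror-image stimulation assays; and links rhythm metrics to emergence
    rank with Spearman correlations, chi-square tests, two-way ANOVA and a
    VIF / Cook's distance / AIC model-selection procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
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
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
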