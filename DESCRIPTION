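Package: circasleep
Title: Circadian and Sleep Analysis of Drosophila Activity Monitor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for circadian and sleep analysis of
    Drosophila Activity Monitor (DAM) beam-crossing recordings. Reads
    TriKinetics-style monitor files, scores rhythmicity and free-running
    period with the Sokolove-Bushell chi-square periodogram, quantifies
    morning and evening anticipation indices, scores sleep by the 5-minute
    immobility rule with per-phase bout statistics, and summarises groups
    with the field's standard statistics (mean +/- SEM, binomial-SD
    proportions, Fisher's exact test, Student's t, one-way ANOVA with Tukey
    HSD). Includes a synthetic DAM-data generator with genotype presets
    emulating wild-type, Pink1 mutant, and Usp14-knockdown phenotypes so
    every analysis stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    parallel,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
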