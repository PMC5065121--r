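Package: barseqfit
Title: Pooled Fitness Competitions by Barcode Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of pooled fitness competition
    experiments read out by barcode sequencing (bar-seq). Generates
    synthetic chemostat competitions of barcoded strain pools with known
    per-generation selection coefficients, demultiplexes and counts
    barcode reads by exact matching, estimates per-strain relative
    fitness by log-linear regression of normalized barcode frequencies
    over the steady-state window, classifies the distribution of fitness
    effects against a control-calibrated cutoff, and joins fitness
    screens to mutation catalogs from experimental-evolution studies
    (recurrence, ploidy contingency tests, gene-length bias, driver
    prediction). Includes deterministic haploid selection dynamics used
    to reason about detection and fixation of beneficial mutations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
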