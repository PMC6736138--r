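Package: hdxdiff
Title: Statistical Filtering and Visualization of Differential HDX-MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for differential hydrogen-deuterium
    exchange mass spectrometry (HDX-MS). Reads DynamX-style peptide-level
    "state" and "difference" CSV exports, derives global confidence limits
    for differential deuterium uptake from pooled per-timepoint dispersion,
    replicate count and a two-tailed Student-t critical value, and
    classifies peptides as protected, deprotected or non-significant.
    Flattens peptide-level results to per-residue coverage, redundancy and
    uptake tracks, renders Woods plots and coverage/redundancy maps, and
    emits PyMOL command scripts that project the results onto protein
    structures. Includes a ground-truthed synthetic data generator with
    saturating first-order exchange kinetics for validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    IRanges,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
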