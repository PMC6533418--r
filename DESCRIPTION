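Package: phosphodrift
Title: Paired-Specimen Analysis of Multiplex Barcode-Antibody Protein Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multiplex antibody-barcode protein counts
    (nCounter-style panels) from paired FFPE specimens. Implements the full
    control-based normalization chain (ERCC positive-control scaling,
    negative-probe and IgG background subtraction, housekeeping
    normalization, half-minimum zero imputation, log2 transform),
    small-sample exact nonparametric tests (Wilcoxon signed-rank,
    Mann-Whitney U, Spearman correlation with permutation p-values),
    paired core-cut versus surgical-excision differential summaries,
    concordance with immunohistochemistry scores, two-way hierarchical
    clustering on Spearman-correlation distance, dilution-replicate QC,
    and a synthetic-cohort generator that emulates fixation-delay-driven
    phosphoprotein decay and stress-response induction for calibration
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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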