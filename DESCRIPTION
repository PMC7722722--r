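Package: immunotme
Title: Immune Landscape Analysis of Paired Tumor and Adjacent Tissue at Single-Cell Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling the tumor immune microenvironment from paired
    tumor/adjacent single-cell RNA-seq and TCR-seq cohorts. Provides quality
    control filtering of UMI count matrices, log2(count+1) and per-gene z-score
    normalization, gene-signature scoring (including correlation-anchored
    signature derivation), paired alpha/beta TCR clonotype assignment with
    clonal-expansion and cross-cluster sharing analytics, per-sample
    ligand-receptor co-expression scoring with an exact small-cohort Wilcoxon
    significance call, cell-type composition tables with paired tissue tests,
    and a seeded synthetic-cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
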