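Package: wharv
Title: Window-Based HERV Alignment Scoring for Single-Cell Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Windowed coverage scoring of autonomous human endogenous
    retrovirus (HERV) loci and neighboring host genes from cell-type-filtered
    single-cell read alignments. Implements the Window-based HERV Alignment
    (WHA) classifier (usable-window counting, window-similarity gating, and
    positive/negative locus calls), pangenome-control filtering of cohort
    presence matrices, and the comparative statistics used for cohort
    contrasts (Welch t-tests on window counts and depth; one-way ANOVA with
    Tukey HSD for host genes). Includes a fully specified synthetic-cohort
    generator (reference catalog, barcoded SAM alignments, ground-truth
    manifest) so the entire pipeline is testable without access to raw
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
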