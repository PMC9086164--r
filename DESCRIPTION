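Package: editscape
Title: Detection and Differential Analysis of A-to-I RNA Editing from Base Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies adenosine-to-inosine (A-to-I) RNA editing from per-site
    base counts, applies a high-confidence filter (editing level >= 1% in at
    least two samples, or membership in a known-editing-site catalogue),
    assigns functional consequences from a transcript model, profiles the
    nucleotide context around editing sites, tests for differential editing
    between groups with the Kruskal-Wallis test, and correlates editing levels
    with host-gene expression (TPM, Spearman). Ships a synthetic-data
    generator that emulates a two-group brain RNA-seq study design with
    planted motif, differential and cis-regulatory structure, plus
    machine-readable ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
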