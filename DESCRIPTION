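Package: sortscreen
Title: Analysis and Simulation of FACS-Sorted Pooled CRISPRi Activity Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sort-based (FACS bin) pooled CRISPR interference
    screens that read out a stimulus-induced cellular response, such as
    calcium-dependent CaMPARI photoconversion in enteroendocrine cells.
    Covers the full analysis path: sgRNA library manifests and sample
    sheets, protospacer counting from FASTQ reads, bin-vs-bin and
    dropout enrichment statistics, rank-sum tests of gene sgRNA sets
    against non-targeting controls, an empirical false discovery rate
    built from resampled negative-control quasi-genes, phenotype scores
    and hit classification, cross-screen concordance and gene-set
    over-representation. A screen simulator with planted per-gene
    effects, tail sorting and overdispersed sequencing counts supports
    end-to-end calibration and power studies, and companion functions
    quantify the accompanying single-cell readouts: flow-cytometry
    red/green ratios, dF/F0 imaging traces, four-parameter logistic
    dose-response fits, ddCt knockdown and relative hormone secretion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
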