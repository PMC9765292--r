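Package: crispriscreen
Title: Design and Analysis of Genome-Wide Bacterial CRISPRi Fitness Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooled CRISPR interference (CRISPRi) screens in
    bacteria: genome-wide single guide RNA library design against NGG
    protospacer-adjacent motifs with strand-aware retention rules for coding
    sequences and intergenic regions, spacer extraction and counting from
    amplicon sequencing reads, median-ratio normalization, gene-level
    depletion scoring with a robust-rank-aggregation permutation layer,
    cross-condition regression of gene scores with standardized-residual
    outlier calling, luciferase reporter screen scoring, genome-weighted COG
    functional profiling, and a synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
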