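Package: rootMethylome
Title: Windowed DMR Calling, TE Enrichment and Promoter
    Methylation-Expression Correlation for Root-Initiation Methylomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a bisulfite-sequencing analysis pipeline for
    developmental methylome studies: weighted methylation summaries in the
    CG, CHG and CHH contexts, 50-bp windowed differential-methylation
    calling with Fisher's exact test and a replicate-consistency filter,
    annotation of DMRs against genes, promoters and transposable elements,
    DMR-associated TE length enrichment against random control windows,
    RNA-seq-side filters (transcribed-gene counts, DEG and
    coefficient-of-variation filters, classical MDS), and best-promoter-bin
    CHH methylation versus expression correlation with FDR control. A
    synthetic-data generator with planted ground truth emulates
    two-replicate BS-seq count data and matched expression matrices so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    MethylSeq, Software
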