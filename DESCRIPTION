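Package: lncripe
Title: Long Non-Coding RNA Identification and Characterization for
    Climacteric Fruit-Ripening Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for genome-wide long non-coding RNA
    (lncRNA) analysis in a four-stage climacteric fruit-ripening RNA-seq
    design (growing, ripening, climacteric, post-climacteric; three
    biological replicates per stage). Implements candidate filtering
    (length, exon count, expression), an open-reading-frame based coding
    potential veto with optional external assessor flags, positional
    classification into intergenic and antisense lncRNAs, pairwise
    stage differential expression with Benjamini-Hochberg correction and
    Venn accounting, cis target prediction by 100-kb genomic windowing,
    trans target prediction by Pearson correlation screening,
    hypergeometric term enrichment, signed co-expression network assembly
    with hierarchical-clustering heatmap ordering, and 2^-ddCt qPCR
    validation arithmetic. Ships a synthetic-data generator that plants
    recoverable lncRNAs, cis/trans pairs, differential expression and
    enriched terms so the whole pipeline is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    IRanges,
    GenomicRanges,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
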