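Package: intronTF
Title: Transcription Factor Binding to First Introns
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-centered analysis of transcription factor (TF) binding to
    first introns in nematode genomes. Classifies "conventional" genes from
    GFF3/FASTA annotation and decomposes them into promoter, exon and intron
    fragments; maps orthologous exons between two species by translated local
    alignment and measures cross-species intron length conservation;
    predicts TF binding sites with a position-weight-matrix energy
    (occupancy) model and calls sites conserved between orthologous regions;
    assigns ChIP peak midpoints to gene fragments; computes Jaccard
    protein-DNA-interaction similarity and its relation to co-expression;
    and fits exponential and hypo-exponential models of regulatory
    in-degree. Includes a synthetic two-species genome and network
    generator so the full pipeline can be exercised and validated without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
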