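Package: MEIdetect
Title: Detection of Non-Reference Retrotransposon Insertion Polymorphisms
    from Paired-End Whole-Genome Sequencing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls non-reference mobile element insertions (Alu, L1, SVA,
    LTR retrotransposons) from coordinate-sorted paired-end BAM files by
    classifying discordant read pairs and soft-clipped reads against a
    retrotransposon consensus library, clustering the evidence into
    candidate loci, recalibrating soft-clip breakpoints to recover target
    site duplications, and genotyping each insertion from the balance of
    reference-spanning and insertion-supporting reads. Includes subfamily
    annotation via diagnostic nucleotides, orientation and inserted-length
    annotation from locally assembled evidence contigs, a TE-insertion
    read simulator with ground-truth output and a built-in provenance
    ("perfect") aligner, an evaluation harness with positional-tolerance
    call matching, and allele-frequency-spectrum utilities with the
    neutral theta/i expectation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
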