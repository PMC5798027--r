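Package: cnscan
Title: Conserved Noncoding Sequence Discovery from Reference-Anchored
    Multiple Alignments
Version: 0.1.0
Authors@R:
    person("CNS", "Toolkit Developers", email = "cnscan@example.org",
           role = c("aut", "cre"))
Description: A toolkit for phylogenetic footprinting in plant genomes.
    Computes per-base, per-clade conservation scores from reference-anchored
    multiple alignments (MAF), calls conserved noncoding sequences (CNSs)
    with threshold/merge/length rules, annotates them against gene models,
    tests for purifying selection using population SNP minor-allele-frequency
    spectra and SNP-density depletion, and computes IUPAC motif enrichment
    within CNS categories.  Includes a synthetic-data generator that emulates
    reference genomes, multi-species alignments with planted conserved
    elements, gene models, and population variants for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
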