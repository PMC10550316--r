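Package: somarna
Title: Somatic Mutation Inference and Mutation-Rate Modeling from Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers somatic single-nucleotide mutations from multi-accession
    bulk RNA-seq pileup data and models how genomic features predict genewise
    mutation counts. Implements candidate-site selection, germline removal and
    a twelve-part artifact-filter cascade (region masks, splice-junction
    proximity, binomial sequencing-error and variant-allele-frequency tests,
    five Mann-Whitney read-attribute bias tests, polynucleotide-run proximity,
    cross-accession recurrence, outlier-accession exclusion and restriction to
    unambiguous UTR/exonic regions); computes base-aware effective gene
    lengths, normalized transcriptional depth, transcriptional strand classes,
    GC content, replication-timing and overlap-weighted chromatin signals; and
    fits a LASSO-penalized Poisson generalized linear model of genewise
    mutation counts with an effective-length offset, plus a locus recurrence
    model, alternate-allele entropy, 96-channel trinucleotide mutational
    catalogs and a deterministic signature factorization. A synthetic-data
    generator emits annotation, reference sequence, germline variants, signal
    tracks and per-accession pileups with planted truths so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    glmnet,
    stats,
    utils,
    tools,
    methods,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
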