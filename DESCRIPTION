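Package: protointrons
Title: Discovery and Characterization of Protointrons from Splice-Junction
    Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and characterizes protointrons: rare, poorly conserved,
    inefficiently spliced intron-like sequences revealed when spliceosome
    competition is relieved (e.g. by rapamycin repression of ribosomal protein
    genes in budding yeast). Consumes STAR-style splice-junction tables,
    genome FASTA, GFF3/BED12 annotation and bedGraph coverage or conservation
    tracks; applies a filter cascade (read support, GT/GC donors, GAG acceptor
    context, branchpoint geometry, jackpot and mismap artifact checks), merges
    surviving events into intron locations, and classifies them against gene
    context. Quantifies splicing with junction/intron/exon2 coverage indices
    and percent-spliced estimates, profiles splice-signal position weight
    matrices and conservation windows, computes codon-permutation hexamer
    depletion Z-scores, tests the association between 5'UTR introns and
    upstream ORFs, and ships a synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
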