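Package: enrichmap
Title: Genomic Coordinate Annotation, P-Value Aggregation, and Gene Set
    Enrichment for Livestock Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline toolkit for the biological interpretation of
    coordinate-based and gene-list-based omics signals. Parses an
    Ensembl-dialect GTF, derives computed gene features (introns, splice
    donors/acceptors, upstream/downstream windows, transcription start
    sites) from the canonical ones, and builds a strand-aware interval
    index for annotating nucleotide-level signals such as CpG sites or
    SNPs. Aggregates site-level P-values to gene level via nearest-gene
    assignment and Fisher, Sidak, Simes, or min-FDR combination. Performs
    hypergeometric overrepresentation analysis with an enforced study
    background, running-sum (Kolmogorov-Smirnov style) gene set
    enrichment analysis with permutation significance, and
    transcription-factor target enrichment with optional ortholog
    mapping. Includes gene identifier conversion across Ensembl, Entrez,
    symbol, and human ortholog namespaces, GMT readers and writers, and a
    deterministic synthetic-fixture generator for end-to-end testing
    without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
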