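Package: RaggedAssay
Title: Lossless Ragged Genomic-Range Containers with Matrix Reductions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Copy number segments, somatic mutations, methylation and
    open-chromatin calls are "ragged": every sample is measured at its own
    set of genomic coordinates, so the data are not matrix-shaped. RaggedAssay
    stores such per-sample range collections losslessly -- subsetting only
    rewrites integer row and column indices, never the underlying ranges --
    and converts them on demand to rectangular sample-by-feature matrices via
    four well-defined reductions: one row per observed range (sparseAssay),
    identical ranges merged (compactAssay), ranges fragmented at the union of
    endpoints (disjoinAssay), and summarization onto user-supplied query
    regions such as genes (qreduceAssay). Readers for SEG, BED, minimal MAF,
    minimal VCF and GFF3 query models, matrix writers (TSV, MatrixMarket), a
    seeded synthetic-fixture generator and a command-line interface are
    included.
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
    SummarizedExperiment,
    Matrix,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'range-algebra.R'
    'RaggedAssay-class.R'
    'RaggedAssay-methods.R'
    'reductions.R'
    'io.R'
    'fixtures.R'
    'cli.R'
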