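# RaggedAssay

Lossless containers for "ragged" genomic-range data — measurements made at
different genomic coordinates in every sample — with efficient, well-specified
conversions to rectangular matrices.

Copy-number segments, somatic mutations, methylation calls and open-chromatin
regions all arrive as one set of ranges per sample, so they are not
matrix-shaped, while most downstream statistics want a features × samples
matrix. Summarizing early is lossy and inflates memory, so `RaggedAssay`
stores the per-sample ranges exactly as observed and defers rectangularization
to the moment of analysis.

## The data model

A `RaggedAssay` object holds:

- **assays** — a `GRangesList`, one `GRanges` per sample, all sharing one
  metadata-column schema (the assay columns, e.g. `seg.mean` or
  `Variant_Classification`);
- **rowidx / colidx** — integer index vectors into the concatenation of all
  samples' ranges and into the samples. Every subsetting operation
  (`[`, `subsetByOverlaps`) rewrites only these vectors; the ranges are never
  copied or dropped, so any invertible chain of subsets can be undone and the
  original data recovered exactly;
- **colData** — per-sample phenotype data, keyed by sample name.

Coordinates are 1-based, fully closed; conversion to/from BED's 0-based
half-open convention happens only at the BED I/O boundary. Strand is stored
but ignored by default in overlap and disjoin computations (`ignore.strand`
switches this).

## The four reductions

For a container with value column *v*, background value *b* (the entry for
cells with no observation):

| Reduction | Rows | Cell (r, j) |
|---|---|---|
| `sparseAssay` | one per range observation | *v* if observation r belongs to sample j, else *b* |
| `compactAssay` | one per distinct (contig, start, end, strand) | sample j's value for that exact range, else *b* |
| `disjoinAssay` | disjoint fragments at the union of all range endpoints | `simplify(values of sample j's ranges covering r)`, else *b* |
| `qreduceAssay` | user query ranges (genes) in given order | `simplify(scores, query-trimmed ranges, qrange)` over sample j's overlapping ranges, else *b* |

`compactAssay` differs from `sparseAssay` only when identical input ranges
exist. `qreduceAssay`'s summarizer takes exactly three arguments; two are
built in:

- `coverageWeightedMean(scores, ranges, qrange)` =
  Σᵢ scoreᵢ·wᵢ / Σᵢ wᵢ with wᵢ the width of the query-trimmed range — the
  standard gene-level segmented copy-number summary;
- `nonsilentBinary(silent.categories = "Silent")` — with `background = 0`,
  codes a gene/sample cell 1 when at least one overlapping mutation is
  non-silent and 0 otherwise.

Numeric matrices can be returned sparse-backed (`sparse = TRUE`,
`Matrix::sparseMatrix`); absent cells are then the implicit zero.

## Worked example

```r
library(RaggedAssay)

a <- makeRange("chr1", c(1, 8), c(5, 9), values = list(score = c(1, 3)))
b <- makeRange("chr1", 1, 5,            values = list(score = 2))
ra <- RaggedAssay(A = a, B = b)

sparseAssay(ra, "score")
#>          A  B
#> chr1:1-5 1 NA
#> chr1:8-9 3 NA
#> chr1:1-5 NA 2

compactAssay(ra, "score")   # identical ranges share one row
#>          A  B
#> chr1:1-5 1  2
#> chr1:8-9 3 NA

seg <- makeRange("chr1", c(1, 101), c(100, 200), values = list(cn = c(2, 4)))
gene <- makeRange("chr1", 51, 150); names(gene) <- "GENE1"
qreduceAssay(RaggedAssay(S = seg), gene, coverageWeightedMean, "cn")
#>       S
#> GENE1 3
```

The last value is the coverage-weighted mean over the gene: the gene covers
50 bases of the copy-number-2 segment and 50 of the copy-number-4 segment,
(2·50 + 4·50)/100 = 3.

## File formats

Readers: `readSeg` (segmented copy number, 1-based closed by default with an
explicit 0-based dialect switch), `readBed` (0-based half-open, converted),
`readMafMin` (minimal MAF column subset: `Tumor_Sample_Barcode`,
`Chromosome`, `Start_Position`, `End_Position`, `Variant_Classification`;
names configurable), `readVcfMin` (the INFO/FORMAT field feeding the assay is
a required argument), `readQueryRanges` (gene models from BED or GFF3).
Writers: `writeSeg`, `writeBed`, and `writeMatrix`/`readMatrix` (TSV, or
MatrixMarket with `.rownames`/`.colnames` sidecars).

## Command line

A thin CLI over the same functions is installed at
`system.file("scripts", "ragged-matrix.R", package = "RaggedAssay")`:

```sh
Rscript ragged-matrix.R fixture --seed 7 --samples 3 --out toy.seg
Rscript ragged-matrix.R disjoin --seg toy.seg --fun mean --out disjoin.tsv
Rscript ragged-matrix.R qreduce --maf toy.maf --query genes.bed \
    --fun any-nonsilent --background 0 --out mutations.tsv
```

Subcommands: `sparse`, `compact`, `disjoin`, `qreduce`, `fixture`, `info`.
Usage errors exit 2, data errors exit 1; `--help` lists all flags.

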