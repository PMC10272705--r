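---
title: "Ragged genomic ranges and their matrix reductions"
author: "RaggedAssay authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ragged genomic ranges and their matrix reductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RaggedAssay)
```

# The problem

Assays that report genomic intervals — segmented DNA copy number, somatic
mutations, methylation segments, open-chromatin peaks — measure every sample
at its own coordinates. The resulting data are *ragged*: a list of
per-sample range sets rather than a matrix. Downstream statistics almost
always want a features × samples matrix, but summarizing early is lossy
(fragment boundaries, per-observation metadata and within-sample replicates
disappear) and can inflate memory enormously. The design principle of this
package is therefore: **store losslessly, rectangularize late, and make the
rectangularization rules explicit**.

# The container

`RaggedAssay` wraps a `GRangesList` (one `GRanges` per sample, all sharing
one metadata-column schema) together with two integer index vectors,
`rowidx` into the concatenation of all samples' ranges and `colidx` into the
samples. Every form of subsetting — square-bracket with integers, masks or
names; `subsetByOverlaps` — composes with these vectors and touches nothing
else. Consequences:

- subsetting is O(index length) and never copies range data;
- indices may repeat and permute, so views can duplicate rows or columns;
- any subset chain whose composed indices form a permutation is invertible,
  and coercing any view back to a `GRangesList` (`as(x, "GRangesList")`)
  materializes exactly the selected observations, per sample, in view order.

Assumptions the container enforces rather than guesses: sample names are
unique; all samples expose identical metadata columns in identical order
(a mismatch is an error, not a silent union, because the reductions need one
coherent value column); `colData` rows correspond 1:1 to samples by name.

## Conventions

- **Coordinates** are 1-based, fully closed everywhere inside the package;
  width = end − start + 1. The only conversion point is BED I/O (0-based
  half-open), delegated to `rtracklayer`. SEG files are read as 1-based
  closed by default with an explicit `zero.based` switch, because SEG in the
  wild is ambiguous and guessing silently would corrupt coordinates by one.
- **Strand** is stored faithfully but ignored by default in all overlap and
  disjoin computations, with `ignore.strand = FALSE` as the opt-in. The
  motivating data types (copy number, mutation calls) are unstranded;
  keeping strand out of the algebra by default avoids surprising row splits.
  This also settles a genuinely open design point — whether disjoin
  fragments should split where strands differ: by default they do not;
  respecting strand makes fragments strand-specific.
- **Row names** are range strings: `"contig:start-end"`, with `":strand"`
  appended only when strand is not `"*"` and the start-end part collapsed to
  a single position for width-1 ranges.
- **Contig order** defaults to order of first appearance across samples when
  no `Seqinfo` is declared — deterministic without requiring a genome
  declaration — and to the declared `Seqinfo` order otherwise.
- **Internal indices are 1-based**, the native R convention; a single
  internal convention avoids off-by-one drift, and the textual interfaces
  (file formats) each document their own convention.

# The four reductions

All reductions read the current view (so repeated columns duplicate sample
columns) and place `background` in cells with no observation. The default
background is the missing sentinel of the value type; mutation binarization
overrides it with 0.

**`sparseAssay`** — one row per range observation across all samples.
Identical ranges in different samples stay on separate rows; a fresh
container yields exactly one non-background entry per row. Row order is view
(rowidx) order.

**`compactAssay`** — one row per *distinct* (contig, start, end, strand).
It differs from the sparse reduction only when identical input ranges exist.
Within one sample, duplicated identical ranges collapse silently when their
values agree and raise an error when two non-missing values conflict — the
ambiguity must not be resolved silently. Rows are sorted by (contig order,
start, end, strand), strand ranked `+` < `-` < `*`.

**`disjoinAssay`** — all view ranges, across all samples, are fragmented at
the union of their start and end + 1 positions per contig. This is the
minimal pairwise-disjoint fragment set covering exactly the covered bases,
because coverage composition can only change at one of those positions. The
cell for (fragment, sample) applies `simplify` (e.g. `mean`) to the values
of that sample's ranges covering the fragment; overlapping ranges within one
sample all contribute, with no deduplication. Fragments are sorted as in
`compactAssay`.

**`qreduceAssay`** — rows are user query ranges (typically genes) in given
order; row names prefer query names over range strings when both exist. For
each (query, sample), the sample's overlapping ranges are trimmed to the
query *before* the three-argument summarizer
`simplify(scores, ranges, qrange)` is called — the widths the summarizer
sees are trimmed widths, which is what makes coverage weighting correct.
When nothing overlaps, the cell is `background` and the summarizer is not
called, so `nonsilentBinary` plus `background = 0` gives the standard
gene × patient 0/1 mutation coding: 1 when at least one overlapping
mutation's classification falls outside `silent.categories` (default
`"Silent"`, fully configurable — no genome-annotation knowledge is hidden in
the package), 0 for silent-only or no mutations. Flanking regions are the
caller's responsibility: pre-expand the query ranges; no flank logic is
built in.

`coverageWeightedMean` computes Σ scoreᵢ·wᵢ / Σ wᵢ over trimmed widths wᵢ.
When a sample's contributors tile the covered region without overlapping
each other, this equals the per-base mean over covered bases; when they
overlap, each contributor still counts with its full trimmed width.

## Numerical and degenerate-input choices

- A missing (`NA`) value *contributing* to `disjoinAssay` or `qreduceAssay`
  is an error at reduction time, never silently treated as background;
  missing values are representable in the container and pass through the
  sparse/compact reductions unchanged.
- Summarizer exceptions are re-raised with (row, column) context.
- Sparse backing uses `Matrix::sparseMatrix`, whose absent entries are
  implicit zeros; `sparse = TRUE` therefore requires numeric values and
  background `NA` or 0, realizes background 0, and stores observed `NA`
  values explicitly. Character assays never get sparse backing (error, not
  warning).
- An empty container reduces to a 0 × 0 matrix; an empty query gives a
  0-row matrix; an empty subset keeps its column count.
- A bare `NA` background adopts the input value type; any other background
  fixes the cell type, and summarizer results may promote it.

# The synthetic-fixture generator

`generateFixture` exists so that every test, demo and the acceptance script
run without downloads, and its modes emulate the shapes that drive the
reductions:

- `independent` — each sample draws ranges independently (mutation-like
  scatter); widths are exponential with mean one tenth of the contig, so
  both sharp and broad events occur;
- `shared-breakpoints` — all samples draw endpoints from one global
  breakpoint set per contig (about 9 breakpoints), guaranteeing identical
  ranges across samples — the regime where `compactAssay` differs from
  `sparseAssay`;
- `tiled` — per-sample non-overlapping segments covering each contig
  end-to-end, the shape of segmented copy-number output.

Values are Gaussian (default mean 0, sd 1, a centered log-ratio-like scale)
or categorical (variant-classification-like labels). `duplicate.rate` copies
that fraction of ranges identically into another sample; within one sample,
coordinate duplicates are value-equalized so the compact precondition (no
conflicting duplicate values within a sample) holds by construction.
Defaults — 3 samples, 4–12 ranges per sample, 2 contigs of 10 kb — are small
enough for per-base verification yet large enough to exercise every overlap
regime. Each call runs on a private RNG stream seeded by `seed` and restores
the caller's RNG state.

What the generator does *not* emulate: real chromosome lengths and numbers,
correlated breakpoints between samples short of full sharing, realistic
mutation spectra, missing-data patterns, or strandedness. Passing tests
therefore demonstrate the correctness of the range algebra, index
bookkeeping and reduction semantics — not robustness to the quirks of any
particular consortium dataset.

# Verification strategy

The test suite checks the implementation against *independent* brute-force
oracles that expand ranges base by base on short contigs (≤ 10⁴ bases):
overlap pairs from a per-base occupancy table, disjoin fragments from
per-base covering-set labels, `disjoinAssay(mean)` and
`qreduceAssay(coverageWeightedMean)` from per-base value-sum and coverage
arrays (for the weighted mean the identity
Σ scoreᵢ·wᵢ / Σ wᵢ = total per-base value sum / total per-base coverage over
the query makes the check exact). The acceptance tests run these on 200
random containers (2–4 samples, up to ~80 ranges, contigs up to 10 kb —
sizes chosen so the whole sweep completes in about 1.5 minutes on one CPU),
alongside 100-trial checks of the compact/sparse relationship, lossless
subset-inversion round trips, the subset composition law, exhaustive
enumeration of the mutation coding over a 3-gene × 2-sample × 3-category
toy (729 assignments, end-to-end through MAF files), 50-fixture I/O round
trips, and sparse/dense parity at background 0. Tolerances are 1e-9
wherever floating point is involved and exact elsewhere.

# Known limitations

- No nucleotide sequences, liftover, gapped/spliced ranges, or circular
  contigs; no out-of-core backing.
- The minimal VCF reader handles scalar INFO/FORMAT fields and derives
  footprints as [POS, POS + nchar(REF) − 1]; symbolic ALTs and END-based
  structural-variant footprints are out of scope. Which field feeds the
  assay is deliberately a required argument — there is no universal default.
- The minimal MAF reader reads only the five columns above.
- `mcols<-` and `colData<-` through views with repeated indices are refused
  (ambiguous write-back targets).
- Recurrence statistics (GISTIC-like), eQTL analysis and consequence
  annotation are downstream concerns, not provided here.
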