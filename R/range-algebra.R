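## Interval-algebra surface used by every reduction. Coordinates are 1-based,
## fully closed throughout the package; conversion to/from 0-based half-open
## happens only at the BED boundary (see io.R). Strand is stored but ignored
## by default in overlap and disjoin computations.

#' Build a validated genomic range
#'
#' Constructs a [GenomicRanges::GRanges] object from parallel coordinate
#' vectors, applying the package's coordinate contract: 1-based, fully closed
#' intervals with `start >= 1` and `end >= start`, strand one of `+`, `-`,
#' `*`, and (when a [GenomeInfoDb::Seqinfo] with contig lengths is supplied)
#' `end` no greater than the contig length.
#'
#' @param contig Character vector of contig (chromosome) names.
#' @param start,end Integer vectors of 1-based inclusive positions.
#' @param strand Strand codes, recycled; one of `"+"`, `"-"`, `"*"`.
#' @param values Optional named list of metadata columns (numeric or
#'   character vectors, recycled to the number of ranges).
#' @param seqinfo Optional [GenomeInfoDb::Seqinfo]; when it carries lengths,
#'   coordinates are checked against them.
#' @return A `GRanges` of the same length as `contig`.
#' @examples
#' makeRange("chr1", 1, 10)
#' makeRange("chr2", 100, 200, "+", values = list(score = 2.5))
#' @export
makeRange <- function(contig, start, end, strand = "*", values = list(),
                      seqinfo = NULL) {
    contig <- as.character(contig)
    start <- as.integer(start)
    end <- as.integer(end)
    if (any(is.na(contig)) || any(!nzchar(contig)))
        stop("contig names must be non-empty")
    if (any(is.na(start)) || any(is.na(end)))
        stop("invalid coordinates: start/end must be non-missing integers")
    if (any(start < 1L))
        stop("invalid coordinates: start must be >= 1")
    if (any(end < start))
        stop("invalid coordinates: end must be >= start")
    strand <- as.character(strand)
    if (!all(strand %in% c("+", "-", "*")))
        stop("invalid strand: must be one of '+', '-', '*'")
    gr <- GRanges(contig, IRanges(start, end), strand = strand)
    if (length(values)) {
        if (is.null(names(values)) || any(!nzchar(names(values))))
            stop("metadata values must be named")
        mcols(gr) <- DataFrame(lapply(values, rep, length.out = length(gr)))
    }
    if (!is.null(seqinfo)) {
        missing <- setdiff(seqlevels(gr), seqlevels(seqinfo))
        if (length(missing))
            stop("unknown contig(s): ", paste(missing, collapse = ", "))
        lens <- seqlengths(seqinfo)[as.character(seqnames(gr))]
        bad <- !is.na(lens) & end > lens
        if (any(bad))
            stop("range end exceeds contig length for: ",
                 paste(unique(as.character(seqnames(gr))[bad]), collapse = ", "))
        seqlevels(gr) <- seqlevels(seqinfo)
        seqinfo(gr) <- seqinfo
    }
    gr
}

#' Find overlapping pairs between two range collections
#'
#' Closed-interval overlap: ranges overlap when they share a contig and at
#' least one base (`q.start <= s.end && s.start <= q.end`). With
#' `ignore.strand = FALSE` strands must additionally be compatible (equal, or
#' either `*`).
#'
#' @param query,subject `GRanges` collections.
#' @param ignore.strand Ignore strand when testing overlap (default `TRUE`).
#' @return A two-column integer `data.frame` with columns `queryHits` and
#'   `subjectHits` (1-based indices into `query` and `subject`), sorted by
#'   query index then subject index.
#' @examples
#' q <- makeRange("chr1", 1, 10)
#' s <- makeRange("chr1", 10, 20)
#' findRangeOverlaps(q, s)   # the single shared base 10 counts
#' @export
findRangeOverlaps <- function(query, subject, ignore.strand = TRUE) {
    ## disjoint contig sets are an ordinary no-overlap case, not a warning
    hits <- suppressWarnings(
        findOverlaps(query, subject, ignore.strand = ignore.strand))
    df <- data.frame(queryHits = queryHits(hits), subjectHits = subjectHits(hits))
    df[order(df$queryHits, df$subjectHits), , drop = FALSE]
}

#' Intersect two single ranges
#'
#' @param a,b `GRanges` of length 1.
#' @return A `GRanges` of length 1 (`[max(starts), min(ends)]` on the shared
#'   contig, strand `*` unless both inputs agree) when the ranges overlap,
#'   otherwise an empty `GRanges` (length 0).
#' @examples
#' rangeIntersect(makeRange("chr1", 1, 100), makeRange("chr1", 51, 150))
#' @export
rangeIntersect <- function(a, b) {
    stopifnot(length(a) == 1L, length(b) == 1L)
    if (as.character(seqnames(a)) != as.character(seqnames(b)))
        return(GRanges())
    s <- max(start(a), start(b))
    e <- min(end(a), end(b))
    if (s > e)
        return(GRanges())
    st <- if (as.character(strand(a)) == as.character(strand(b)))
        as.character(strand(a)) else "*"
    GRanges(as.character(seqnames(a)), IRanges(s, e), strand = st)
}

#' Fragment ranges at the union of their endpoints
#'
#' Computes, per contig, the minimal set of pairwise-disjoint fragments whose
#' boundaries come from the union of input start and `end + 1` positions,
#' covering exactly the covered bases, together with the input ranges covering
#' each fragment.
#'
#' @param x A `GRanges` collection.
#' @param ignore.strand When `TRUE` (default) strand does not split
#'   fragments and the fragments are unstranded.
#' @return A list with elements `fragments` (a `GRanges`, sorted by contig
#'   order then start, no metadata) and `sourceMap` (an
#'   [IRanges::IntegerList]; for each fragment the 1-based indices of the
#'   input ranges covering it).
#' @examples
#' x <- makeRange(c("chr1", "chr1"), c(1, 6), c(10, 15))
#' disjoinRanges(x)
#' @export
disjoinRanges <- function(x, ignore.strand = TRUE) {
    if (!length(x))
        return(list(fragments = GRanges(), sourceMap = IRanges::IntegerList()))
    frag <- disjoin(x, with.revmap = TRUE, ignore.strand = ignore.strand)
    ord <- rangeOrder(frag)
    frag <- frag[ord]
    revmap <- mcols(frag)$revmap
    mcols(frag) <- NULL
    list(fragments = frag, sourceMap = revmap)
}

#' Sorting permutation for a range collection
#'
#' Stable ordering by (contig position in `contig.order`, start, end, strand)
#' with strand ranked `+` < `-` < `*`.
#'
#' @param x A `GRanges`.
#' @param contig.order Character vector giving the canonical contig ordering;
#'   defaults to `seqlevels(x)`. Every observed contig must be present.
#' @return An integer permutation such that `x[rangeOrder(x)]` is sorted.
#' @examples
#' x <- makeRange(c("chr2", "chr1"), c(5, 100), c(6, 200))
#' rangeOrder(x)  # chr1 first
#' @export
rangeOrder <- function(x, contig.order = seqlevels(x)) {
    contig <- as.character(seqnames(x))
    pos <- match(contig, contig.order)
    if (anyNA(pos))
        stop("unknown contig(s): ",
             paste(unique(contig[is.na(pos)]), collapse = ", "))
    ## GRanges strand levels are already ("+", "-", "*")
    order(pos, start(x), end(x), as.integer(strand(x)), method = "radix")
}
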