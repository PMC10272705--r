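#' RaggedAssay: a lossless container for ragged genomic-range data
#'
#' `RaggedAssay` holds one set of genomic ranges per sample (a
#' [GenomicRanges::GRangesList]) together with two integer index vectors,
#' `rowidx` (into the concatenation of all samples' ranges) and `colidx`
#' (into the samples). All subsetting — square-bracket, overlap-based —
#' only rewrites these index vectors; the underlying ranges are never copied,
#' dropped or reordered, so the original data remain fully recoverable from
#' any subset whose composed indices are invertible. Rectangular views are
#' produced on demand by [sparseAssay()], [compactAssay()], [disjoinAssay()]
#' and [qreduceAssay()].
#'
#' All samples must share one metadata-column schema (identical `mcols`
#' column names, in identical order); those columns are the assays of the
#' container. Sample-level phenotype data live in `colData`, one row per
#' sample, keyed by sample name.
#'
#' @slot assays `GRangesList`, one element per sample, uniquely named.
#' @slot rowidx Integer indices into `unlist(assays)`; may repeat/permute.
#' @slot colidx Integer indices into the samples; may repeat/permute.
#' @slot colData `DataFrame` with one row per underlying sample, rownames
#'   equal to the sample names.
#'
#' @param ... `GRanges` objects (named), a list of `GRanges`, or a single
#'   `GRangesList` — one element per sample.
#' @param colData Optional `DataFrame`/`data.frame` of sample phenotype data
#'   whose rownames are exactly the sample names (any order).
#' @param seqinfo Optional [GenomeInfoDb::Seqinfo]. When absent, contigs are
#'   registered in order of first appearance across the concatenated samples.
#'
#' @return `RaggedAssay()` returns a `RaggedAssay` object with identity
#'   row/column indices.
#'
#' @examples
#' a <- makeRange("chr1", c(1, 8), c(5, 9), values = list(score = c(1, 3)))
#' b <- makeRange("chr1", 1, 5, values = list(score = 2))
#' ra <- RaggedAssay(A = a, B = b)
#' dim(ra)
#' sparseAssay(ra, "score")
#'
#' @aliases RaggedAssay
#' @export RaggedAssay
#' @exportClass RaggedAssay
.RaggedAssay <- setClass("RaggedAssay",
    contains = "Annotated",
    representation(
        assays = "GRangesList",
        rowidx = "integer",
        colidx = "integer",
        colData = "DataFrame"
    )
)

## total number of underlying range observations
.nRanges <- function(x) sum(lengths(x@assays))

## unlisted underlying ranges (no name mangling)
.unlisted <- function(x) unlist(x@assays, use.names = FALSE)

## sample index of every underlying range observation
.sampleOfRange <- function(x) rep(seq_along(x@assays), lengths(x@assays))

## shared metadata-column schema
.schema <- function(x) colnames(mcols(.unlisted(x)))

setValidity("RaggedAssay", function(object) {
    msg <- NULL
    nm <- names(object@assays)
    if (length(object@assays)) {
        if (is.null(nm) || any(!nzchar(nm)))
            msg <- c(msg, "all samples must be named")
        else if (anyDuplicated(nm))
            msg <- c(msg, "duplicate sample name(s): ",
                     paste(unique(nm[duplicated(nm)]), collapse = ", "))
        schemas <- lapply(object@assays, function(gr) colnames(mcols(gr)))
        if (length(unique(schemas)) > 1L)
            msg <- c(msg, "all samples must share one metadata-column schema")
    }
    nr <- .nRanges(object)
    if (length(object@rowidx) &&
        (min(object@rowidx) < 1L || max(object@rowidx) > nr))
        msg <- c(msg, "rowidx out of bounds")
    if (length(object@colidx) &&
        (min(object@colidx) < 1L || max(object@colidx) > length(object@assays)))
        msg <- c(msg, "colidx out of bounds")
    cdn <- rownames(object@colData)
    if (nrow(object@colData) != length(object@assays) ||
        !identical(as.character(if (is.null(cdn)) character(0) else cdn),
                   as.character(if (is.null(nm)) character(0) else unname(nm))))
        msg <- c(msg, "colData rows must correspond 1:1 to samples, in order")
    if (is.null(msg)) TRUE else paste(msg, collapse = "; ")
})

RaggedAssay <- function(..., colData = NULL, seqinfo = NULL) {
    args <- list(...)
    if (length(args) == 1L && is(args[[1L]], "GRangesList")) {
        grl <- args[[1L]]
    } else {
        if (length(args) == 1L && is.list(args[[1L]]) &&
            !is(args[[1L]], "GRanges"))
            args <- args[[1L]]
        if (!length(args) || !all(vapply(args, is, logical(1), "GRanges")))
            stop("supply GRanges objects, a list of GRanges, or a GRangesList")
        schemas <- lapply(args, function(gr) colnames(mcols(gr)))
        if (length(unique(schemas)) > 1L)
            stop("inconsistent metadata-column schema across samples: ",
                 "all samples must expose identical columns in identical ",
                 "order")
        grl <- GRangesList(args, compress = TRUE)
    }
    nm <- names(grl)
    if (length(grl)) {
        if (is.null(nm))
            nm <- paste0("sample", seq_along(grl))
        blank <- !nzchar(nm)
        nm[blank] <- paste0("sample", which(blank))
        if (anyDuplicated(nm))
            stop("duplicate sample name(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", "))
        names(grl) <- nm
    }
    ## contig registry: declared seqinfo, or order of first appearance
    if (!is.null(seqinfo)) {
        missing <- setdiff(seqlevels(grl), seqlevels(seqinfo))
        if (length(missing))
            stop("unknown contig(s) not in seqinfo: ",
                 paste(missing, collapse = ", "))
        seqlevels(grl) <- seqlevels(seqinfo)
        seqinfo(grl) <- seqinfo
    } else {
        observed <- unique(as.character(seqnames(unlist(grl, use.names = FALSE))))
        if (length(observed))
            seqlevels(grl) <- observed
    }
    if (is.null(colData)) {
        colData <- DataFrame(row.names = names(grl))
    } else {
        colData <- as(colData, "DataFrame")
        if (is.null(rownames(colData)) ||
            !setequal(rownames(colData), names(grl)) ||
            nrow(colData) != length(grl))
            stop("colData sample keys must match sample names exactly")
        colData <- colData[match(names(grl), rownames(colData)), , drop = FALSE]
    }
    .RaggedAssay(
        assays = grl,
        rowidx = seq_len(sum(lengths(grl))),
        colidx = seq_along(grl),
        colData = colData
    )
}
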