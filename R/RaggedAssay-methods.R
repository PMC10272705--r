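## Accessors and index-only subsetting. Everything here manipulates rowidx /
## colidx; the underlying GRangesList is never modified.

## resolve a user row/column selector to positive integer indices
.resolveIndex <- function(idx, n, names, what = "index") {
    if (is.logical(idx)) {
        if (length(idx) != n)
            stop(what, ": logical mask length ", length(idx),
                 " does not match extent ", n)
        return(which(idx))
    }
    if (is.character(idx)) {
        pos <- match(idx, names)
        if (anyNA(pos))
            stop(what, ": unknown name(s): ",
                 paste(unique(idx[is.na(pos)]), collapse = ", "))
        return(pos)
    }
    if (is.numeric(idx)) {
        if (anyNA(idx))
            stop(what, ": NA index")
        idx <- as.integer(idx)
        if (all(idx <= 0L))
            idx <- seq_len(n)[idx]
        if (any(idx < 1L) || any(idx > n))
            stop(what, ": index out of bounds [1, ", n, "]")
        return(idx)
    }
    stop(what, ": unsupported selector type ", class(idx)[1L])
}

#' @describeIn RaggedAssay Dimensions: `c(length(rowidx), length(colidx))`.
#' @export
setMethod("dim", "RaggedAssay", function(x)
    c(length(x@rowidx), length(x@colidx)))

#' @describeIn RaggedAssay Number of range observations in the current view
#'   (equal to `nrow(x)`).
#' @export
setMethod("length", "RaggedAssay", function(x) length(x@rowidx))

#' @describeIn RaggedAssay Row names are range strings
#'   (`"contig:start-end"`, with `":strand"` appended when strand is not
#'   `"*"`); column names are sample names.
#' @export
setMethod("dimnames", "RaggedAssay", function(x) {
    list(as.character(granges(rowRanges(x))),
         unname(names(x@assays))[x@colidx])
})

#' @describeIn RaggedAssay The ranges of the current view: the concatenated
#'   sample ranges reordered/filtered by `rowidx`, metadata columns included.
#' @export
setMethod("rowRanges", "RaggedAssay", function(x, ...)
    .unlisted(x)[x@rowidx])

#' @describeIn RaggedAssay Range metadata of the current view (one row per
#'   range observation).
#' @export
setMethod("mcols", "RaggedAssay", function(x, use.names = FALSE, ...)
    mcols(rowRanges(x), use.names = use.names, ...))

#' @describeIn RaggedAssay Replace range metadata through the current view
#'   (requires a non-repeating `rowidx`).
#' @export
setReplaceMethod("mcols", "RaggedAssay", function(x, ..., value) {
    if (anyDuplicated(x@rowidx))
        stop("cannot set mcols through a view with repeated rows")
    u <- .unlisted(x)
    value <- as(value, "DataFrame")
    if (nrow(value) != length(x@rowidx))
        stop("replacement mcols must have one row per view row")
    full <- mcols(u)
    full[x@rowidx, ] <- value
    mcols(x@assays@unlistData) <- full
    validObject(x)
    x
})

#' @describeIn RaggedAssay Sample phenotype data, rows aligned to `colidx`.
#' @export
setMethod("colData", "RaggedAssay", function(x, ...)
    x@colData[x@colidx, , drop = FALSE])

#' @describeIn RaggedAssay Replace sample phenotype data; rownames of
#'   `value` must match the current column names exactly.
#' @export
setReplaceMethod("colData", c("RaggedAssay", "DataFrame"), function(x, ..., value) {
    if (anyDuplicated(x@colidx))
        stop("cannot set colData through a view with repeated columns")
    cur <- unname(names(x@assays))[x@colidx]
    if (is.null(rownames(value)) || !setequal(rownames(value), cur) ||
        nrow(value) != length(cur))
        stop("colData sample keys must match current sample names exactly")
    value <- value[match(cur, rownames(value)), , drop = FALSE]
    if (setequal(x@colidx, seq_along(x@assays))) {
        ## full view: replace the whole table (columns may change)
        full <- value[match(names(x@assays), rownames(value)), , drop = FALSE]
        rownames(full) <- names(x@assays)
        x@colData <- full
    } else {
        ## partial view: update the selected rows; untouched samples keep
        ## their rows, so the column schema must agree
        if (!identical(colnames(value), colnames(x@colData)))
            stop("colData columns must match the existing table when ",
                 "setting through a column-subset view")
        new <- x@colData
        new[x@colidx, ] <- value
        x@colData <- new
    }
    validObject(x)
    x
})

#' @describeIn RaggedAssay Contig registry of the underlying ranges.
#' @export
setMethod("seqinfo", "RaggedAssay", function(x) seqinfo(x@assays))

#' @describeIn RaggedAssay Replace the contig registry.
#' @export
setReplaceMethod("seqinfo", "RaggedAssay",
    function(x, new2old = NULL,
             pruning.mode = c("error", "coarse", "fine", "tidy"), value) {
        assays <- x@assays
        seqlevels(assays) <- seqlevels(value)
        seqinfo(assays) <- value
        x@assays <- assays
        x
    })

#' @describeIn RaggedAssay Lazy square-bracket subsetting: composes the
#'   row/column selectors with the current index vectors. Selectors may be
#'   integer (repetition and permutation allowed), logical masks, or
#'   row/column names.
#' @param i,j Row and column selectors.
#' @param drop Ignored (always `FALSE`).
#' @export
setMethod("[", "RaggedAssay", function(x, i, j, ..., drop = FALSE) {
    dn <- dimnames(x)
    if (!missing(i)) {
        ii <- .resolveIndex(i, length(x@rowidx), dn[[1L]], "row")
        x@rowidx <- x@rowidx[ii]
    }
    if (!missing(j)) {
        jj <- .resolveIndex(j, length(x@colidx), dn[[2L]], "column")
        x@colidx <- x@colidx[jj]
    }
    x
})

#' @describeIn RaggedAssay For each view row, is it overlapped by at least
#'   one range in `ranges`?
#' @param query,ranges For `overlapsAny`/`subsetByOverlaps`: the container
#'   and a `GRanges` of query regions.
#' @param ignore.strand Ignore strand when testing overlap (default `TRUE`).
#' @export
setMethod("overlapsAny", c("RaggedAssay", "GenomicRanges"),
    function(query, subject, maxgap = -1L, minoverlap = 0L,
             type = c("any", "start", "end", "within", "equal"), ...,
             ignore.strand = TRUE) {
        if (!length(subject))
            return(logical(nrow(query)))
        suppressWarnings(
            overlapsAny(granges(rowRanges(query)), subject,
                        maxgap = maxgap, minoverlap = minoverlap,
                        type = match.arg(type),
                        ignore.strand = ignore.strand))
    })

#' @describeIn RaggedAssay Keep the view rows overlapped by `ranges`;
#'   columns are never dropped.
#' @export
setMethod("subsetByOverlaps", c("RaggedAssay", "GenomicRanges"),
    function(x, ranges, maxgap = -1L, minoverlap = 0L,
             type = c("any", "start", "end", "within", "equal"),
             invert = FALSE, ..., ignore.strand = TRUE) {
        keep <- overlapsAny(x, ranges, maxgap = maxgap,
                            minoverlap = minoverlap, type = match.arg(type),
                            ignore.strand = ignore.strand)
        if (invert) keep <- !keep
        x[keep, ]
    })

#' @describeIn RaggedAssay One-paragraph summary.
#' @export
setMethod("show", "RaggedAssay", function(object) {
    d <- dim(object)
    cat("class: RaggedAssay\n",
        "dim: ", d[1L], " ", d[2L], "\n",
        "assays(", length(.schema(object)), "): ",
        paste(.schema(object), collapse = " "), "\n",
        "samples(", length(object@assays), "): ",
        paste(head(names(object@assays), 6L), collapse = " "),
        if (length(object@assays) > 6L) " ..." else "", "\n",
        "contigs: ", paste(head(seqlevels(object@assays), 6L), collapse = " "),
        if (length(seqlevels(object@assays)) > 6L) " ..." else "", "\n",
        sep = "")
})

## Coercion: materialize the current view back into grouped per-sample
## ranges. Each retained sample keeps exactly its rows surviving rowidx, in
## rowidx order; a fresh container round-trips losslessly.
setAs("RaggedAssay", "GRangesList", function(from) {
    u <- .unlisted(from)
    origin <- .sampleOfRange(from)[from@rowidx]
    view <- u[from@rowidx]
    parts <- lapply(from@colidx, function(s) view[origin == s])
    grl <- GRangesList(parts, compress = TRUE)
    names(grl) <- unname(names(from@assays))[from@colidx]
    seqlevels(grl) <- seqlevels(from@assays)
    seqinfo(grl) <- seqinfo(from@assays)
    grl
})

setAs("GRangesList", "RaggedAssay", function(from) RaggedAssay(from))
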