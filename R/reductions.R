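## The four ragged -> matrix reductions. All of them consume the current
## rowidx/colidx view; repeated column indices duplicate sample columns in
## the output. Background (the value of cells with no observation) defaults
## to NA of the assay's value type; sparse backing realizes background 0
## (stored entries may still be NA) and therefore requires numeric values
## and background NA or 0.

## a zero-sample container has no schema; every reduction of it is a 0 x 0
## (or nquery x 0) matrix
.isSchemaless <- function(x) !length(.schema(x)) && !nrow(x) && !ncol(x)

.emptyAssayMatrix <- function(nr = 0L, rownames = character(0)) {
    matrix(numeric(0), nr, 0L, dimnames = list(rownames, character(0)))
}

## resolve an assay selector (name or 1-based ordinal) to a column name
.resolveAssay <- function(x, i) {
    schema <- .schema(x)
    if (is.character(i)) {
        if (length(i) != 1L || !i %in% schema)
            stop("unknown assay column: ", paste(i, collapse = ", "),
                 " (available: ", paste(schema, collapse = ", "), ")")
        return(i)
    }
    if (is.numeric(i) && length(i) == 1L && i >= 1 && i <= length(schema))
        return(schema[[as.integer(i)]])
    stop("assay selector must be a column name or ordinal in [1, ",
         length(schema), "]")
}

.checkSparse <- function(vals, background, sparse) {
    if (!sparse)
        return(invisible(NULL))
    if (!is.numeric(vals))
        stop("sparse backing requires numeric assay values")
    if (!(is.na(background) || identical(as.numeric(background), 0)))
        stop("sparse backing requires background NA or 0 ",
             "(absent cells are implicit zeros)")
    invisible(NULL)
}

## dense matrix filled with background, typed after the assay values
.backgroundMatrix <- function(vals, background, nr, nc, dimnames) {
    bg <- background
    if (length(bg) != 1L)
        stop("background must be a single scalar")
    if (is.character(vals)) bg <- as.character(bg)
    else if (is.numeric(vals)) bg <- as.numeric(bg)
    matrix(bg, nr, nc, dimnames = dimnames)
}

.sparseFromTriplets <- function(ii, jj, xx, nr, nc, dimnames) {
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nr, nc),
                         dimnames = dimnames)
}

#' Sparse reduction: one row per range observation
#'
#' The most direct rectangular view of a ragged container: one row per range
#' observation across all samples (identical ranges in different samples stay
#' on separate rows) and one column per sample. On a fresh container every
#' row has exactly one non-background entry — the value observed in the
#' sample the range came from.
#'
#' @param x A [RaggedAssay].
#' @param i Assay column: a name from the shared metadata schema or a 1-based
#'   ordinal.
#' @param background Scalar placed in cells with no observation. Defaults to
#'   `NA`.
#' @param sparse Return a [Matrix::sparseMatrix] instead of a dense matrix.
#'   Requires numeric values and background `NA` or `0`; absent cells read
#'   as the implicit zero of the sparse representation.
#' @return A matrix (or `dgCMatrix`) with range-string row names and sample
#'   column names.
#' @examples
#' a <- makeRange("chr1", 1, 5, values = list(score = 1))
#' b <- makeRange("chr1", c(1, 8), c(5, 9), values = list(score = c(2, 3)))
#' sparseAssay(RaggedAssay(A = a, B = b), "score")
#' @aliases sparseAssay
#' @export
setMethod("sparseAssay", "RaggedAssay",
    function(x, i = 1L, background = NA, sparse = FALSE) {
        if (.isSchemaless(x))
            return(.emptyAssayMatrix())
        col <- .resolveAssay(x, i)
        vals <- mcols(x)[[col]]
        .checkSparse(vals, background, sparse)
        og <- .sampleOfRange(x)[x@rowidx]
        nr <- nrow(x); nc <- ncol(x)
        dn <- dimnames(x)
        if (sparse) {
            ii <- jj <- integer(0); xx <- numeric(0)
            for (j in seq_len(nc)) {
                sel <- which(og == x@colidx[j])
                ii <- c(ii, sel)
                jj <- c(jj, rep.int(j, length(sel)))
                xx <- c(xx, as.numeric(vals[sel]))
            }
            return(.sparseFromTriplets(ii, jj, xx, nr, nc, dn))
        }
        m <- .backgroundMatrix(vals, background, nr, nc, dn)
        for (j in seq_len(nc)) {
            sel <- og == x@colidx[j]
            m[sel, j] <- vals[sel]
        }
        m
    })

#' Compact reduction: merge identical ranges
#'
#' Like [sparseAssay()], but observations whose ranges are exactly identical
#' (same contig, start, end and strand) share one output row. It differs
#' from the sparse reduction only when identical input ranges exist — e.g.
#' open-chromatin regions repeated across cells, or the same SNP position
#' observed in many samples. Rows are sorted by (contig order, start, end,
#' strand).
#'
#' Within one sample, duplicated identical ranges collapse silently when
#' their values agree and raise an error when two non-missing values
#' conflict.
#'
#' @inheritParams sparseAssay
#' @return A matrix (or `dgCMatrix`) with one row per distinct range.
#' @examples
#' a <- makeRange("chr1", 1, 5, values = list(score = 1))
#' b <- makeRange("chr1", c(1, 8), c(5, 9), values = list(score = c(2, 3)))
#' compactAssay(RaggedAssay(A = a, B = b), "score")
#' @aliases compactAssay
#' @export
setMethod("compactAssay", "RaggedAssay",
    function(x, i = 1L, background = NA, sparse = FALSE) {
        if (.isSchemaless(x))
            return(.emptyAssayMatrix())
        col <- .resolveAssay(x, i)
        vals <- mcols(x)[[col]]
        .checkSparse(vals, background, sparse)
        rr <- granges(rowRanges(x))
        og <- .sampleOfRange(x)[x@rowidx]
        key <- paste(seqnames(rr), start(rr), end(rr), strand(rr))
        firsts <- !duplicated(key)
        urr <- rr[firsts]
        uord <- rangeOrder(urr)
        urr <- urr[uord]
        ukey <- key[firsts][uord]
        kidx <- match(key, ukey)
        nr <- length(urr); nc <- ncol(x)
        dn <- list(as.character(urr), dimnames(x)[[2L]])
        cells <- vector("list", nc)
        for (j in seq_len(nc)) {
            sel <- which(og == x@colidx[j])
            k <- kidx[sel]
            v <- vals[sel]
            if (anyDuplicated(k)) {
                merged <- lapply(split(v, k), function(vv) {
                    uv <- unique(vv[!is.na(vv)])
                    if (length(uv) > 1L)
                        stop("ambiguous duplicate range in sample '",
                             dn[[2L]][j], "': identical ranges carry ",
                             "conflicting values (",
                             paste(uv, collapse = ", "), ")")
                    if (length(uv)) uv else vv[NA_integer_]
                })
                k <- as.integer(names(merged))
                v <- unlist(merged, use.names = FALSE)
            }
            cells[[j]] <- list(k = k, v = v)
        }
        if (sparse) {
            ii <- unlist(lapply(cells, `[[`, "k"), use.names = FALSE)
            jj <- rep.int(seq_len(nc),
                          vapply(cells, function(cc) length(cc$k), integer(1)))
            xx <- as.numeric(unlist(lapply(cells, `[[`, "v"),
                                    use.names = FALSE))
            return(.sparseFromTriplets(ii, jj, xx, nr, nc, dn))
        }
        m <- .backgroundMatrix(vals, background, nr, nc, dn)
        for (j in seq_len(nc))
            m[cells[[j]]$k, j] <- cells[[j]]$v
        m
    })

## shared error wrapper for user summarizers
.callSimplify <- function(fun, args, rowname, colname) {
    tryCatch(do.call(fun, args), error = function(e)
        stop("summarizer failed at row '", rowname, "', column '", colname,
             "': ", conditionMessage(e), call. = FALSE))
}

#' Disjoint reduction: fragment ranges at the union of endpoints
#'
#' All view ranges (across all samples) are fragmented at the union of their
#' start and `end + 1` positions per contig, producing pairwise-disjoint
#' fragments that cover exactly the covered bases. Each output row is one
#' fragment; the cell for (fragment, sample) applies `simplify` to the
#' values of that sample's ranges covering the fragment (a range from the
#' same sample overlapping itself contributes once per observation), or
#' `background` when none covers it. Typical use: fragmenting partially
#' overlapping segmented copy-number calls to find minimal common regions.
#'
#' @inheritParams sparseAssay
#' @param simplify Function mapping a non-empty vector of values (one per
#'   contributing range) to one scalar, e.g. `mean`. Never called on an
#'   empty set. A missing (`NA`) contributing value is an error.
#' @param ignore.strand When `TRUE` (default) strand neither splits
#'   fragments nor restricts contribution.
#' @return A matrix (or `dgCMatrix`) with one row per disjoint fragment,
#'   sorted by (contig order, start, end).
#' @examples
#' a <- makeRange("chr1", 1, 10, values = list(score = 2))
#' b <- makeRange("chr1", 6, 15, values = list(score = 4))
#' disjoinAssay(RaggedAssay(A = a, B = b), mean, "score")
#' @aliases disjoinAssay
#' @export
setMethod("disjoinAssay", "RaggedAssay",
    function(x, simplify, i = 1L, background = NA, sparse = FALSE,
             ignore.strand = TRUE) {
        stopifnot(is.function(simplify))
        if (.isSchemaless(x))
            return(.emptyAssayMatrix())
        col <- .resolveAssay(x, i)
        vals <- mcols(x)[[col]]
        .checkSparse(vals, background, sparse)
        rr <- granges(rowRanges(x))
        og <- .sampleOfRange(x)[x@rowidx]
        dj <- disjoinRanges(rr, ignore.strand = ignore.strand)
        nr <- length(dj$fragments); nc <- ncol(x)
        dn <- list(as.character(dj$fragments), dimnames(x)[[2L]])
        ## expand (fragment, covering view-row) pairs once
        fi <- rep.int(seq_len(nr), lengths(dj$sourceMap))
        ri <- unlist(dj$sourceMap, use.names = FALSE)
        ## a bare NA background takes the input value type; summarizer
        ## results may promote it (a character assay summarized numerically)
        if (is.logical(background) && is.na(background))
            background <- if (is.character(vals)) NA_character_ else NA_real_
        m <- matrix(background, nr, nc, dimnames = dn)
        filled <- matrix(FALSE, nr, nc)
        for (j in seq_len(nc)) {
            keep <- og[ri] == x@colidx[j]
            f <- fi[keep]
            v <- vals[ri[keep]]
            if (anyNA(v))
                stop("missing value in assay '", col, "' contributed to a ",
                     "fragment in column '", dn[[2L]][j], "'")
            groups <- split(v, f)
            for (g in seq_along(groups)) {
                fr <- as.integer(names(groups)[g])
                m[fr, j] <- .callSimplify(simplify, list(groups[[g]]),
                                          dn[[1L]][fr], dn[[2L]][j])
                filled[fr, j] <- TRUE
            }
        }
        if (sparse) {
            idx <- which(filled, arr.ind = TRUE)
            return(.sparseFromTriplets(idx[, 1L], idx[, 2L],
                                       as.numeric(m[idx]), nr, nc, dn))
        }
        m
    })

#' Query reduction: summarize onto regions of interest
#'
#' For each (query range, sample) pair, the sample's view ranges overlapping
#' the query are trimmed to the query and handed to the three-argument
#' summarizer `simplify(scores, ranges, qrange)`; when nothing overlaps the
#' cell is `background` and `simplify` is not called. This is the reduction
#' used to turn segmented copy number into gene-level values
#' ([coverageWeightedMean()]) or somatic mutations into a gene-by-patient
#' 0/1 matrix ([nonsilentBinary()] with `background = 0`).
#'
#' Row order follows the query; row names are the query names when present,
#' range strings otherwise.
#'
#' @inheritParams sparseAssay
#' @param query A `GRanges` of regions of interest (e.g. gene bodies),
#'   optionally named.
#' @param simplify A function of exactly three arguments
#'   `(scores, ranges, qrange)`: the contributing values, the query-trimmed
#'   contributing ranges (same length), and the query range itself. Must
#'   return one scalar. Called only with at least one contributor.
#' @param ignore.strand Ignore strand when matching ranges to queries
#'   (default `TRUE`).
#' @return A dense matrix with one row per query range.
#' @examples
#' seg <- makeRange("chr1", c(1, 101), c(100, 200),
#'                  values = list(cn = c(2, 4)))
#' q <- makeRange("chr1", 51, 150)
#' names(q) <- "GENE1"
#' qreduceAssay(RaggedAssay(A = seg), q, coverageWeightedMean, "cn")
#' @aliases qreduceAssay
#' @export
setMethod("qreduceAssay", "RaggedAssay",
    function(x, query, simplify, i = 1L, background = NA,
             ignore.strand = TRUE) {
        stopifnot(is(query, "GRanges"), is.function(simplify))
        fml <- names(formals(simplify))
        if (!("..." %in% fml) && length(fml) != 3L)
            stop("qreduce summarizer must take exactly three arguments ",
                 "(scores, ranges, qrange)")
        qn <- names(query)
        rown <- if (!is.null(qn) && all(nzchar(qn))) qn
                else as.character(query)
        if (.isSchemaless(x))
            return(.emptyAssayMatrix(length(query), rown))
        col <- .resolveAssay(x, i)
        vals <- mcols(x)[[col]]
        rr <- granges(rowRanges(x))
        og <- .sampleOfRange(x)[x@rowidx]
        nr <- length(query); nc <- ncol(x)
        dn <- list(rown, dimnames(x)[[2L]])
        ## a bare NA background takes the input value type; any other
        ## background fixes the type, and summarizer results may promote it
        if (is.logical(background) && is.na(background))
            background <- if (is.character(vals)) NA_character_ else NA_real_
        m <- matrix(background, nr, nc, dimnames = dn)
        if (!nr || !nc || !length(rr))
            return(m)
        hits <- suppressWarnings(
            findOverlaps(query, rr, ignore.strand = ignore.strand))
        qh <- queryHits(hits); sh <- subjectHits(hits)
        byq <- split(sh, qh)
        for (qi in names(byq)) {
            q <- as.integer(qi)
            rows <- byq[[qi]]
            qr <- query[q]
            ## trim every contributor to the query once
            sub <- rr[rows]
            trimmed <- GRanges(seqnames(sub),
                               IRanges(pmax(start(sub), start(qr)),
                                       pmin(end(sub), end(qr))),
                               strand = strand(sub))
            ogr <- og[rows]
            for (j in seq_len(nc)) {
                keep <- ogr == x@colidx[j]
                if (!any(keep))
                    next
                v <- vals[rows[keep]]
                if (anyNA(v))
                    stop("missing value in assay '", col,
                         "' contributed to query '", rown[q],
                         "' in column '", dn[[2L]][j], "'")
                m[q, j] <- .callSimplify(
                    simplify, list(v, trimmed[keep], qr),
                    rown[q], dn[[2L]][j])
            }
        }
        m
    })

#' Coverage-weighted mean summarizer
#'
#' The canonical query summarizer for segmented copy number: the mean of the
#' contributing values weighted by the widths of the query-trimmed ranges,
#' `sum(scores * width(ranges)) / sum(width(ranges))`. When the contributors
#' tile the covered part of the query without overlapping each other this
#' equals the per-base mean over covered bases.
#'
#' @param scores Numeric values of the contributing ranges.
#' @param ranges Query-trimmed contributing ranges (`GRanges`).
#' @param qrange The query range (unused; present for the three-argument
#'   summarizer contract).
#' @return A single numeric value.
#' @examples
#' coverageWeightedMean(c(2, 4),
#'     makeRange("chr1", c(51, 101), c(100, 150)),
#'     makeRange("chr1", 51, 150))  # 3
#' @export
coverageWeightedMean <- function(scores, ranges, qrange) {
    w <- width(ranges)
    sum(scores * w) / sum(w)
}

#' Non-silent mutation indicator summarizer
#'
#' Factory for the standard somatic-mutation coding: a gene/sample cell is
#' `1` when at least one overlapping mutation has a variant classification
#' outside `silent.categories`, and `0` otherwise. Combine with
#' `background = 0` in [qreduceAssay()] so genes with no mutations also read
#' `0`.
#'
#' @param silent.categories Character vector of classifications treated as
#'   silent. Default `"Silent"`; fully user-configurable.
#' @return A three-argument summarizer suitable for [qreduceAssay()].
#' @examples
#' f <- nonsilentBinary()
#' f("Missense_Mutation", NULL, NULL)  # 1
#' f(c("Silent", "Silent"), NULL, NULL)  # 0
#' @export
nonsilentBinary <- function(silent.categories = "Silent") {
    force(silent.categories)
    function(scores, ranges, qrange)
        as.numeric(any(!scores %in% silent.categories))
}

#' @describeIn RaggedAssay `assay(x, i)` is [sparseAssay()] over column `i`
#'   with the default background.
#' @export
setMethod("assay", c("RaggedAssay", "ANY"),
    function(x, i, withDimnames = TRUE, ...) {
        if (missing(i)) i <- 1L
        sparseAssay(x, i, ...)
    })

#' @describeIn RaggedAssay All assay matrices, one per metadata column.
#' @export
setMethod("assays", "RaggedAssay", function(x, withDimnames = TRUE, ...) {
    nms <- .schema(x)
    SimpleList(setNames(lapply(nms, function(nm) sparseAssay(x, nm)), nms))
})

#' @describeIn RaggedAssay The shared metadata-column names, in order.
#' @export
setMethod("assayNames", "RaggedAssay", function(x, ...) .schema(x))
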