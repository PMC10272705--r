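## Readers for the ragged-range carrier formats and writers for matrix
## output. BED and GFF3 go through rtracklayer (which owns the 0-based
## half-open <-> 1-based closed conversion at the BED boundary); VCF goes
## through VariantAnnotation; MatrixMarket through Matrix. SEG and minimal
## MAF are plain tab-delimited dialects parsed here with explicit per-line
## validation.

.readTab <- function(file) {
    df <- read.delim(file, sep = "\t", header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE, comment.char = "",
                     quote = "")
    attr(df, "line.offset") <- 1L   # header line
    df
}

.requireCols <- function(df, cols, file) {
    missing <- setdiff(cols, colnames(df))
    if (length(missing))
        stop("missing column(s) in ", file, ": ",
             paste(missing, collapse = ", "))
}

## coerce a column to integer/numeric, reporting the first bad line
.numericCol <- function(df, col, file, what = "numeric") {
    raw <- df[[col]]
    out <- suppressWarnings(as.numeric(raw))
    bad <- is.na(out) & !is.na(raw) & nzchar(trimws(as.character(raw)))
    bad <- bad | is.na(raw)
    if (any(bad))
        stop("malformed line ", which(bad)[1L] + attr(df, "line.offset"),
             " in ", file, ": non-", what, " value in column '", col, "'")
    out
}

## group a parsed table into a GRangesList by sample, order of first
## appearance, file order within sample
.groupBySample <- function(sample, gr, value) {
    f <- factor(sample, levels = unique(sample))
    grl <- GRangesList(split(gr, f), compress = TRUE)
    observed <- unique(as.character(seqnames(unlist(grl, use.names = FALSE))))
    if (length(observed))
        seqlevels(grl) <- observed
    grl
}

#' Read segmented copy number (SEG)
#'
#' SEG is a tab-delimited table with one piecewise-constant copy-number
#' segment per line. Column names are configurable; coordinates are taken as
#' 1-based closed by default (the DNAcopy convention) with an explicit
#' switch for 0-based starts — SEG in the wild is ambiguous, so the dialect
#' is never guessed.
#'
#' @param file Path to a tab-delimited SEG file with a header line.
#' @param sample.col,chrom.col,start.col,end.col,value.col Column names;
#'   defaults `"sample"`, `"chrom"`, `"start"`, `"end"`, `"seg.mean"`.
#' @param zero.based Set `TRUE` when starts are 0-based (they are shifted
#'   by +1 on read).
#' @return A `GRangesList`, one element per sample in order of first
#'   appearance, each with a numeric `seg.mean` metadata column; file order
#'   is preserved within sample.
#' @export
readSeg <- function(file, sample.col = "sample", chrom.col = "chrom",
                    start.col = "start", end.col = "end",
                    value.col = "seg.mean", zero.based = FALSE) {
    df <- .readTab(file)
    .requireCols(df, c(sample.col, chrom.col, start.col, end.col, value.col),
                 file)
    if (!nrow(df))
        return(GRangesList())
    start <- .numericCol(df, start.col, file, "integer")
    end <- .numericCol(df, end.col, file, "integer")
    segmean <- .numericCol(df, value.col, file)
    if (zero.based)
        start <- start + 1
    gr <- makeRange(df[[chrom.col]], start, end,
                    values = list(seg.mean = segmean))
    .groupBySample(df[[sample.col]], gr)
}

#' Write segmented copy number (SEG)
#'
#' Writes 1-based closed coordinates with header
#' `sample chrom start end seg.mean` (tab-delimited).
#'
#' @param x A `GRangesList` or [RaggedAssay]; the value column must be
#'   numeric.
#' @param file Output path.
#' @param value.col Metadata column to write; default `"seg.mean"`, falling
#'   back to the first column when absent.
#' @export
writeSeg <- function(x, file, value.col = "seg.mean") {
    if (is(x, "RaggedAssay"))
        x <- as(x, "GRangesList")
    u <- unlist(x, use.names = FALSE)
    if (!value.col %in% colnames(mcols(u))) {
        if (!ncol(mcols(u)))
            stop("no value column to write")
        value.col <- colnames(mcols(u))[1L]
    }
    v <- mcols(u)[[value.col]]
    if (!is.numeric(v))
        stop("SEG value column must be numeric")
    df <- data.frame(
        sample = rep(names(x), lengths(x)),
        chrom = as.character(seqnames(u)),
        start = start(u),
        end = end(u),
        seg.mean = v
    )
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Read a BED file as one sample
#'
#' BED coordinates are 0-based half-open; rtracklayer converts them to the
#' internal 1-based closed convention (a BED record `chr1 0 10` becomes
#' `chr1:1-10`, width 10). The BED score column (column 5), when present,
#' becomes the `score` metadata column.
#'
#' @param file Path to a BED3+ file.
#' @param sample.name Sample name; defaults to the file name without
#'   extension.
#' @return A `GRangesList` of length 1, named `sample.name`.
#' @export
readBed <- function(file, sample.name = sub("\\.[^.]*$", "", basename(file))) {
    gr <- rtracklayer::import(file, format = "BED")
    keep <- intersect("score", colnames(mcols(gr)))
    mcols(gr) <- mcols(gr)[, keep, drop = FALSE]
    setNames(GRangesList(gr), sample.name)
}

#' Write one sample's ranges as BED
#'
#' The internal 1-based closed coordinates are converted back to BED's
#' 0-based half-open convention by rtracklayer. A numeric value column is
#' written as the BED score column.
#'
#' @param x A `GRanges`, or a `GRangesList` of length 1.
#' @param file Output path.
#' @param value.col Metadata column written as score; default `"score"`,
#'   falling back to the first numeric column.
#' @export
writeBed <- function(x, file, value.col = "score") {
    if (is(x, "GRangesList")) {
        stopifnot(length(x) == 1L)
        x <- x[[1L]]
    }
    if (!value.col %in% colnames(mcols(x))) {
        numcols <- colnames(mcols(x))[vapply(mcols(x), is.numeric, logical(1))]
        value.col <- if (length(numcols)) numcols[1L] else NA_character_
    }
    out <- granges(x)
    if (!is.na(value.col))
        mcols(out)$score <- as.numeric(mcols(x)[[value.col]])
    rtracklayer::export(out, file, format = "BED")
    invisible(file)
}

#' Read a minimal MAF-like somatic mutation table
#'
#' Parses the minimal column subset of a Mutation Annotation Format table:
#' tumor barcode, chromosome, 1-based closed start/end, and variant
#' classification. One sample per tumor barcode, in order of first
#' appearance.
#'
#' @param file Path to a tab-delimited file with a header.
#' @param sample.col,chrom.col,start.col,end.col,class.col Column names;
#'   defaults are the standard MAF names `Tumor_Sample_Barcode`,
#'   `Chromosome`, `Start_Position`, `End_Position`,
#'   `Variant_Classification`.
#' @return A `GRangesList` with a character `Variant_Classification`
#'   metadata column.
#' @export
readMafMin <- function(file, sample.col = "Tumor_Sample_Barcode",
                       chrom.col = "Chromosome",
                       start.col = "Start_Position",
                       end.col = "End_Position",
                       class.col = "Variant_Classification") {
    df <- .readTab(file)
    .requireCols(df, c(sample.col, chrom.col, start.col, end.col, class.col),
                 file)
    if (!nrow(df))
        return(GRangesList())
    start <- .numericCol(df, start.col, file, "integer")
    end <- .numericCol(df, end.col, file, "integer")
    gr <- makeRange(df[[chrom.col]], start, end,
                    values = list(
                        Variant_Classification = as.character(df[[class.col]])))
    .groupBySample(df[[sample.col]], gr)
}

#' Read a minimal VCF
#'
#' Each record contributes a range `[POS, POS + nchar(REF) - 1]`. The assay
#' value is taken from `value.selector`: a per-sample FORMAT key yields one
#' sample per VCF genotype column; an INFO key yields a single sample for
#' the whole file. Which field populates the assay is a mandatory user
#' choice — there is no default. Symbolic/structural ALTs (END-based
#' footprints) are out of scope.
#'
#' @param file Path to a VCF 4.x file (plain text or bgzipped).
#' @param value.selector Name of an INFO or FORMAT field.
#' @param sample.name Sample name used for INFO-derived values; defaults to
#'   the file name without extension.
#' @return A `GRangesList` with one metadata column named after
#'   `value.selector`.
#' @export
readVcfMin <- function(file, value.selector,
                       sample.name = sub("\\.vcf(\\.gz)?$", "",
                                         basename(file))) {
    if (missing(value.selector) || !isSingleString(value.selector))
        stop("value.selector (an INFO or FORMAT key) is required")
    vcf <- VariantAnnotation::readVcf(file)
    rr <- granges(SummarizedExperiment::rowRanges(vcf))
    names(rr) <- NULL
    mcols(rr) <- NULL
    geno_keys <- rownames(VariantAnnotation::geno(
        VariantAnnotation::header(vcf)))
    info_keys <- rownames(VariantAnnotation::info(
        VariantAnnotation::header(vcf)))
    if (value.selector %in% geno_keys) {
        g <- VariantAnnotation::geno(vcf)[[value.selector]]
        if (length(dim(g)) > 2L)
            stop("FORMAT field '", value.selector,
                 "' is not scalar per sample")
        parts <- lapply(colnames(g), function(s) {
            out <- rr
            v <- g[, s]
            if (is.list(v))
                v <- vapply(v, function(e) e[1L], v[[1L]][1L])
            mcols(out)[[value.selector]] <- unname(v)
            out
        })
        grl <- GRangesList(setNames(parts, colnames(g)), compress = TRUE)
    } else if (value.selector %in% info_keys) {
        v <- VariantAnnotation::info(vcf)[[value.selector]]
        if (is(v, "List"))
            stop("INFO field '", value.selector, "' is not scalar")
        out <- rr
        mcols(out)[[value.selector]] <- unname(v)
        grl <- GRangesList(setNames(list(out), sample.name), compress = TRUE)
    } else {
        stop("unknown selector '", value.selector,
             "': not an INFO or FORMAT key of ", file)
    }
    grl
}

#' Read query (gene-model) ranges from BED or GFF3
#'
#' Query names come from the BED name column, or from a configurable GFF3
#' attribute (default `Name`, falling back to `ID`, then to the range
#' string). Duplicate names are suffix-deduplicated (`TP53`, `TP53.1`, ...)
#' with a warning.
#'
#' @param file Path to a BED or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @param name.attribute GFF3 attribute holding the feature name.
#' @return A named `GRanges` in file order, metadata dropped.
#' @export
readQueryRanges <- function(file, format = c("auto", "bed", "gff3"),
                            name.attribute = "Name") {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(sub(".*\\.", "", file))
        format <- if (ext %in% c("gff", "gff3")) "gff3" else "bed"
    }
    gr <- rtracklayer::import(file,
                              format = if (format == "bed") "BED" else "GFF3")
    nm <- if (format == "bed") {
        mcols(gr)$name
    } else {
        nm <- mcols(gr)[[name.attribute]]
        id <- mcols(gr)$ID
        if (is.null(nm)) nm <- rep(NA_character_, length(gr))
        ifelse(is.na(nm), if (is.null(id)) NA_character_ else id, nm)
    }
    if (is.null(nm))
        nm <- rep(NA_character_, length(gr))
    nm <- as.character(nm)
    gr <- granges(gr)
    nm[is.na(nm)] <- as.character(gr)[is.na(nm)]
    if (anyDuplicated(nm)) {
        warning("duplicate query names deduplicated: ",
                paste(unique(nm[duplicated(nm)]), collapse = ", "))
        nm <- make.unique(nm)
    }
    names(gr) <- nm
    gr
}

#' Write a reduction matrix
#'
#' TSV output carries row names in the first column (`range`) and sample
#' names in the header; background/missing cells are written as `NA`.
#' MatrixMarket output (numeric matrices only) stores only non-background
#' cells, with two sidecar files `<path>.rownames` and `<path>.colnames`.
#'
#' @param m A dense matrix or `sparseMatrix` from one of the reductions.
#' @param file Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @param background Scalar marking absent cells (omitted from MTX output);
#'   default `NA`.
#' @export
writeMatrix <- function(m, file, format = c("tsv", "mtx"), background = NA) {
    format <- match.arg(format)
    if (is(m, "sparseMatrix")) {
        if (format == "mtx") {
            Matrix::writeMM(m, file)
            writeLines(rownames(m), paste0(file, ".rownames"))
            writeLines(colnames(m), paste0(file, ".colnames"))
            return(invisible(file))
        }
        m <- as.matrix(m)
    }
    if (format == "tsv") {
        df <- data.frame(range = rownames(m), m, check.names = FALSE,
                         stringsAsFactors = FALSE)
        write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
        return(invisible(file))
    }
    if (!is.numeric(m))
        stop("MatrixMarket output requires a numeric matrix")
    absent <- if (is.na(background)) is.na(m) else m == background
    idx <- which(!absent, arr.ind = TRUE)
    sp <- Matrix::sparseMatrix(i = idx[, 1L], j = idx[, 2L],
                               x = as.numeric(m[idx]), dims = dim(m))
    Matrix::writeMM(sp, file)
    writeLines(rownames(m), paste0(file, ".rownames"))
    writeLines(colnames(m), paste0(file, ".colnames"))
    invisible(file)
}

#' Read a reduction matrix written by [writeMatrix()]
#'
#' @param file Path written by [writeMatrix()].
#' @param format `"tsv"` or `"mtx"`.
#' @param background Scalar restored at absent MTX cells; default `NA`.
#' @return A dense matrix with row and column names.
#' @export
readMatrix <- function(file, format = c("tsv", "mtx"), background = NA) {
    format <- match.arg(format)
    if (format == "tsv") {
        df <- read.delim(file, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
        m <- as.matrix(df[, -1L, drop = FALSE])
        rownames(m) <- df[[1L]]
        return(m)
    }
    sp <- as(Matrix::readMM(file), "TsparseMatrix")
    m <- matrix(as.numeric(background), nrow(sp), ncol(sp))
    m[cbind(sp@i + 1L, sp@j + 1L)] <- sp@x
    rownames(m) <- readLines(paste0(file, ".rownames"))
    colnames(m) <- readLines(paste0(file, ".colnames"))
    m
}
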