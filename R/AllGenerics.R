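#' @import methods
#' @importFrom BiocGenerics start end width strand
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata queryHits subjectHits
#'   SimpleList isSingleString
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom GenomicRanges GRanges GRangesList findOverlaps disjoin granges
#'   seqnames
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqinfo<- seqlevels seqlevels<-
#'   seqlengths seqnames<-
#' @importFrom SummarizedExperiment assay assays assayNames colData colData<-
#'   rowRanges
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.delim write.table head
#' @importClassesFrom S4Vectors Annotated DataFrame
#' @importClassesFrom GenomicRanges GRanges GRangesList GenomicRanges
NULL

#' @rdname sparseAssay
#' @export
setGeneric("sparseAssay", function(x, i = 1L, ...) standardGeneric("sparseAssay"))

#' @rdname compactAssay
#' @export
setGeneric("compactAssay", function(x, i = 1L, ...) standardGeneric("compactAssay"))

#' @rdname disjoinAssay
#' @export
setGeneric("disjoinAssay", function(x, simplify, i = 1L, ...)
    standardGeneric("disjoinAssay"))

#' @rdname qreduceAssay
#' @export
setGeneric("qreduceAssay", function(x, query, simplify, i = 1L, ...)
    standardGeneric("qreduceAssay"))
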