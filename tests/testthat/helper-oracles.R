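## Independent brute-force oracles, all built on plain base-R per-base
## position tables (never on interval algebra), plus small random-input
## helpers. Contigs are assumed short (<= 1e4 bases) so full per-base
## expansion is cheap.

## random GRanges on chr1..chrK of length L, optional values
randomRanges <- function(n, n.contigs = 2, L = 1000, stranded = FALSE,
                         values = TRUE) {
    ct <- paste0("chr", sample(n.contigs, n, replace = TRUE))
    st <- sample(L, n, replace = TRUE)
    en <- pmin(L, st + sample(0:(L %/% 5), n, replace = TRUE))
    sd <- if (stranded) sample(c("+", "-", "*"), n, replace = TRUE) else "*"
    v <- if (values) list(score = round(stats::rnorm(n), 3)) else list()
    makeRange(ct, st, en, sd, values = v)
}

## per-base occupancy table: for each contig a L x n logical matrix, base b
## covered by range i
.occupancy <- function(gr, contigs, L) {
    occ <- lapply(contigs, function(ct) matrix(FALSE, L, length(gr)))
    names(occ) <- contigs
    cts <- as.character(GenomicRanges::seqnames(gr))
    st <- BiocGenerics::start(gr)
    en <- BiocGenerics::end(gr)
    for (i in seq_along(gr))
        occ[[cts[i]]][st[i]:en[i], i] <- TRUE
    occ
}

## brute-force overlap pairs via shared marked bases
oracleOverlaps <- function(query, subject, L = 1000, ignore.strand = TRUE) {
    contigs <- union(as.character(unique(GenomicRanges::seqnames(query))),
                     as.character(unique(GenomicRanges::seqnames(subject))))
    if (!length(query) || !length(subject))
        return(data.frame(queryHits = integer(0), subjectHits = integer(0)))
    qocc <- .occupancy(query, contigs, L)
    socc <- .occupancy(subject, contigs, L)
    qs <- as.character(BiocGenerics::strand(query))
    ss <- as.character(BiocGenerics::strand(subject))
    pairs <- list()
    for (ct in contigs) {
        for (qi in seq_along(query)) {
            if (!any(qocc[[ct]][, qi])) next
            shared <- colSums(socc[[ct]] & qocc[[ct]][, qi]) > 0
            for (si in which(shared)) {
                if (!ignore.strand &&
                    qs[qi] != "*" && ss[si] != "*" && qs[qi] != ss[si])
                    next
                pairs[[length(pairs) + 1L]] <- c(qi, si)
            }
        }
    }
    if (!length(pairs))
        return(data.frame(queryHits = integer(0), subjectHits = integer(0)))
    df <- as.data.frame(do.call(rbind, pairs))
    names(df) <- c("queryHits", "subjectHits")
    df <- unique(df[order(df$queryHits, df$subjectHits), , drop = FALSE])
    rownames(df) <- NULL
    df
}

## per-base labeling disjoin oracle: label each base with the set of
## covering inputs, merge maximal runs of equal non-empty label
oracleDisjoin <- function(gr, L = 1000) {
    contigs <- unique(as.character(GenomicRanges::seqnames(gr)))
    allocc <- .occupancy(gr, contigs, L)
    frag <- list(); src <- list()
    for (ct in contigs) {
        occ <- allocc[[ct]]
        label <- apply(occ, 1L, function(row) paste(which(row), collapse = ","))
        r <- rle(label)
        pos <- cumsum(c(1L, r$lengths))
        for (k in seq_along(r$values)) {
            if (!nzchar(r$values[k])) next
            s <- pos[k]; e <- pos[k + 1L] - 1L
            frag[[length(frag) + 1L]] <- c(ct, s, e)
            src[[length(src) + 1L]] <-
                as.integer(strsplit(r$values[k], ",")[[1L]])
        }
    }
    list(fragments = frag, sourceMap = src)
}

## per-sample per-base value-sum and coverage-count arrays
.baseArrays <- function(gr, vals, contigs, L) {
    sum_ <- lapply(contigs, function(ct) numeric(L))
    cnt_ <- lapply(contigs, function(ct) numeric(L))
    names(sum_) <- names(cnt_) <- contigs
    cts <- as.character(GenomicRanges::seqnames(gr))
    st <- BiocGenerics::start(gr)
    en <- BiocGenerics::end(gr)
    for (i in seq_along(gr)) {
        idx <- st[i]:en[i]
        sum_[[cts[i]]][idx] <- sum_[[cts[i]]][idx] + vals[i]
        cnt_[[cts[i]]][idx] <- cnt_[[cts[i]]][idx] + 1
    }
    list(sum = sum_, cnt = cnt_)
}

## per-base oracle for disjoinAssay(mean): every base of a fragment carries
## its sample's covering values; fragment value = per-base mean there
oracleDisjoinAssayMean <- function(ra, L) {
    contigs <- GenomeInfoDb::seqlevels(seqinfo(ra))
    grl <- as(ra, "GRangesList")
    rr <- unlist(grl, use.names = FALSE)
    ## fragments straight from the endpoint-union definition: coverage can
    ## only change at a start or just past an end, so every inter-breakpoint
    ## interval is uniformly covered or uncovered
    allct <- as.character(GenomicRanges::seqnames(rr))
    allst <- BiocGenerics::start(rr)
    allen <- BiocGenerics::end(rr)
    total <- .baseArrays(rr, rep(0, length(rr)), contigs, L)
    fct <- character(0); fst <- integer(0); fen <- integer(0)
    for (ct in contigs) {
        on <- allct == ct
        if (!any(on)) next
        bp <- sort(unique(c(allst[on], allen[on] + 1L)))
        cs <- bp[-length(bp)]
        ce <- bp[-1L] - 1L
        covered <- total$cnt[[ct]][cs] > 0
        fct <- c(fct, rep(ct, sum(covered)))
        fst <- c(fst, cs[covered])
        fen <- c(fen, ce[covered])
    }
    ## width-1 ranges print as "contig:pos", wider ones as "contig:start-end"
    rn <- ifelse(fst == fen, sprintf("%s:%d", fct, fst),
                 sprintf("%s:%d-%d", fct, fst, fen))
    out <- matrix(NA_real_, length(fct), length(grl),
                  dimnames = list(rn, names(grl)))
    for (j in seq_along(grl)) {
        gr <- grl[[j]]
        if (!length(gr)) next
        arr <- .baseArrays(gr, S4Vectors::mcols(gr)[[1L]], contigs, L)
        for (f in seq_along(fct)) {
            ct <- fct[f]; b <- fst[f]
            if (arr$cnt[[ct]][b] > 0)
                out[f, j] <- arr$sum[[ct]][b] / arr$cnt[[ct]][b]
        }
    }
    out
}

## per-base oracle for qreduceAssay(coverageWeightedMean): total per-base
## value sum over the query's bases divided by total per-base coverage
oracleQreduceWeightedMean <- function(ra, query, L) {
    grl <- as(ra, "GRangesList")
    contigs <- GenomeInfoDb::seqlevels(seqinfo(ra))
    qn <- names(query)
    rn <- if (!is.null(qn) && all(nzchar(qn))) qn else as.character(query)
    out <- matrix(NA_real_, length(query), length(grl),
                  dimnames = list(rn, names(grl)))
    for (j in seq_along(grl)) {
        gr <- grl[[j]]
        if (!length(gr)) next
        arr <- .baseArrays(gr, S4Vectors::mcols(gr)[[1L]], contigs, L)
        for (q in seq_along(query)) {
            ct <- as.character(GenomicRanges::seqnames(query[q]))
            if (!ct %in% contigs) next
            idx <- BiocGenerics::start(query[q]):BiocGenerics::end(query[q])
            idx <- idx[idx <= L]
            den <- sum(arr$cnt[[ct]][idx])
            if (den > 0)
                out[q, j] <- sum(arr$sum[[ct]][idx]) / den
        }
    }
    out
}

## GRangesList equality on everything the container stores
expect_grl_equal <- function(a, b) {
    expect_identical(names(a), names(b))
    for (k in seq_along(a)) {
        expect_identical(as.character(GenomicRanges::seqnames(a[[k]])),
                         as.character(GenomicRanges::seqnames(b[[k]])))
        expect_identical(BiocGenerics::start(a[[k]]), BiocGenerics::start(b[[k]]))
        expect_identical(BiocGenerics::end(a[[k]]), BiocGenerics::end(b[[k]]))
        expect_identical(as.character(BiocGenerics::strand(a[[k]])),
                         as.character(BiocGenerics::strand(b[[k]])))
        expect_equal(as.data.frame(S4Vectors::mcols(a[[k]])),
                     as.data.frame(S4Vectors::mcols(b[[k]])))
    }
}
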