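twoSample <- function() {
    RaggedAssay(
        A = makeRange("chr1", 1, 5, values = list(score = 1)),
        B = makeRange("chr1", c(1, 8), c(5, 9), values = list(score = c(2, 3))))
}

test_that("sparseAssay keeps one row per range observation", {
    m <- sparseAssay(twoSample(), "score")
    expect_equal(dim(m), c(3L, 2L))
    expect_equal(rownames(m), c("chr1:1-5", "chr1:1-5", "chr1:8-9"))
    expect_equal(unname(m),
                 matrix(c(1, NA, NA, NA, 2, 3), 3, 2))
    ## exactly one observation per row on a fresh container; column counts
    ## equal per-sample range counts
    expect_equal(rowSums(!is.na(m)), setNames(rep(1, 3), rownames(m)))
    expect_equal(colSums(!is.na(m)), c(A = 1, B = 2))

    e <- sparseAssay(RaggedAssay(GRangesList()))
    expect_equal(dim(e), c(0L, 0L))

    expect_error(sparseAssay(twoSample(), "missing_col"), "unknown assay")
})

test_that("sparse and dense backing agree elementwise", {
    set.seed(101)
    for (rep in 1:10) {
        ra <- generateFixture(n.samples = 3, duplicate.rate = 0.2,
                              seed = 400 + rep)
        d <- sparseAssay(ra, "score", background = 0)
        s <- sparseAssay(ra, "score", sparse = TRUE)
        expect_equal(unname(as.matrix(s)), unname(d))
        expect_identical(dimnames(s), dimnames(d))
        dc <- compactAssay(ra, "score", background = 0)
        sc <- compactAssay(ra, "score", sparse = TRUE)
        expect_equal(unname(as.matrix(sc)), unname(dc))
    }
    expect_error(sparseAssay(
        RaggedAssay(A = makeRange("chr1", 1, 2,
                                  values = list(call = "x"))),
        "call", sparse = TRUE), "numeric")
})

test_that("compactAssay merges identical ranges only", {
    m <- compactAssay(twoSample(), "score")
    expect_equal(dim(m), c(2L, 2L))
    expect_equal(m["chr1:1-5", ], c(A = 1, B = 2))
    expect_equal(m["chr1:8-9", ], c(A = NA_real_, B = 3))

    ## all-distinct ranges: equals sparseAssay up to row permutation
    set.seed(111)
    for (rep in 1:5) {
        repeat {
            ra <- generateFixture(n.samples = 3, seed = 500 + rep * 7)
            rr <- granges(rowRanges(ra))
            if (!anyDuplicated(as.character(rr))) break
        }
        sp <- sparseAssay(ra, "score")
        cp <- compactAssay(ra, "score")
        expect_equal(nrow(cp), nrow(sp))
        expect_equal(cp[match(rownames(sp), rownames(cp)), , drop = FALSE],
                     sp[, , drop = FALSE],
                     ignore_attr = FALSE)
    }

    ## within-sample duplicates: equal values collapse, conflicts error
    dup <- RaggedAssay(A = makeRange(c("chr1", "chr1"), c(1, 1), c(5, 5),
                                     values = list(score = c(1, 1))))
    expect_equal(unname(compactAssay(dup, "score")), matrix(1))
    conflict <- RaggedAssay(A = makeRange(c("chr1", "chr1"), c(1, 1), c(5, 5),
                                          values = list(score = c(1, 2))))
    expect_error(compactAssay(conflict, "score"), "ambiguous duplicate")
})

test_that("compactAssay rows are sorted and never exceed sparseAssay rows", {
    set.seed(121)
    for (rep in 1:10) {
        ra <- generateFixture(n.samples = 3, duplicate.rate = 0.4,
                              overlap.mode = "shared-breakpoints",
                              seed = 600 + rep)
        sp <- sparseAssay(ra, "score")
        cp <- compactAssay(ra, "score")
        expect_lte(nrow(cp), nrow(sp))
        rr <- granges(rowRanges(ra))
        expect_equal(nrow(cp), length(unique(paste(seqnames(rr), start(rr),
                                                   end(rr), strand(rr)))))
        ord <- rangeOrder(GRanges(rownames(cp)))
        expect_equal(ord, seq_len(nrow(cp)))
    }
})

test_that("disjoinAssay fragments across samples and applies simplify", {
    ra <- RaggedAssay(
        A = makeRange("chr1", 1, 10, values = list(score = 2)),
        B = makeRange("chr1", 6, 15, values = list(score = 4)))
    m <- disjoinAssay(ra, mean, "score")
    expect_equal(rownames(m), c("chr1:1-5", "chr1:6-10", "chr1:11-15"))
    expect_equal(m[, "A"], c("chr1:1-5" = 2, "chr1:6-10" = 2,
                             "chr1:11-15" = NA))
    expect_equal(m[, "B"], c("chr1:1-5" = NA, "chr1:6-10" = 4,
                             "chr1:11-15" = 4))

    ## one sample with self-overlapping ranges: simplify combines them
    self <- RaggedAssay(A = makeRange(c("chr1", "chr1"), c(1, 6), c(10, 15),
                                      values = list(score = c(1, 3))))
    ms <- disjoinAssay(self, mean, "score")
    expect_equal(ms["chr1:6-10", "A"], 2)

    ## pairwise-disjoint input: disjoin equals compact
    set.seed(131)
    for (rep in 1:5) {
        ra <- generateFixture(n.samples = 2, overlap.mode = "independent",
                              seed = 700 + rep)
        rr <- granges(rowRanges(ra))
        hits <- findRangeOverlaps(rr, rr)
        if (nrow(hits) != length(rr)) next  # only all-disjoint draws
        expect_equal(disjoinAssay(ra, mean, "score"),
                     compactAssay(ra, "score"))
    }
})

test_that("disjoinAssay(mean) matches the per-base oracle", {
    set.seed(141)
    for (rep in 1:10) {
        L <- 1000
        ra <- generateFixture(n.samples = 3, contig.length = L,
                              overlap.mode = sample(c("independent",
                                                      "tiled"), 1),
                              seed = 800 + rep)
        got <- disjoinAssay(ra, mean, "score")
        want <- oracleDisjoinAssayMean(ra, L = L)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("qreduceAssay trims to the query and honors the no-overlap contract", {
    seg <- makeRange("chr1", c(1, 101), c(100, 200),
                     values = list(cn = c(2, 4)))
    ra <- RaggedAssay(S = seg)
    q <- makeRange("chr1", 51, 150)
    names(q) <- "GENE1"
    m <- qreduceAssay(ra, q, coverageWeightedMean, "cn")
    expect_equal(rownames(m), "GENE1")
    expect_equal(m["GENE1", "S"], 3)   # (2*50 + 4*50) / 100

    ## no-overlap query: background, simplify never called
    bomb <- function(scores, ranges, qrange) stop("must not be called")
    far <- makeRange("chr2", 1, 10)
    expect_equal(unname(qreduceAssay(ra, far, bomb, "cn")),
                 matrix(NA_real_))
    expect_equal(unname(qreduceAssay(ra, far, bomb, "cn", background = 0)),
                 matrix(0))

    ## query equal to the single range: summarizer sees it untrimmed
    one <- RaggedAssay(S = makeRange("chr1", 10, 20,
                                     values = list(cn = 5)))
    probe <- function(scores, ranges, qrange) {
        stopifnot(length(scores) == 1L, start(ranges) == start(qrange),
                  end(ranges) == end(qrange))
        coverageWeightedMean(scores, ranges, qrange)
    }
    expect_equal(unname(qreduceAssay(one, makeRange("chr1", 10, 20), probe,
                                     "cn")), matrix(5))

    ## arity contract
    expect_error(qreduceAssay(ra, q, function(a, b) a, "cn"),
                 "three arguments")
    ## unnamed queries fall back to range strings; names win otherwise
    m2 <- qreduceAssay(ra, granges(unname(q)), coverageWeightedMean, "cn")
    expect_equal(rownames(m2), "chr1:51-150")
})

test_that("qreduceAssay(weighted mean) matches the per-base oracle", {
    set.seed(151)
    for (rep in 1:10) {
        L <- 1000
        ra <- generateFixture(n.samples = 3, contig.length = L,
                              overlap.mode = "tiled", seed = 900 + rep)
        q <- randomRanges(6, n.contigs = 2, L = L, values = FALSE)
        got <- qreduceAssay(ra, q, coverageWeightedMean, "score")
        want <- oracleQreduceWeightedMean(ra, q, L = L)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("summarizer errors carry row and column context", {
    ra <- twoSample()
    expect_error(disjoinAssay(ra, function(v) stop("boom"), "score"),
                 "row 'chr1:1-5', column 'A'.*boom")
    q <- makeRange("chr1", 1, 10)
    expect_error(qreduceAssay(ra, q, function(s, r, qr) stop("boom"),
                              "score"), "row 'chr1:1-10', column 'A'.*boom")
    ## a missing contributing value is an error, not silently background
    na <- RaggedAssay(A = makeRange("chr1", 1, 5,
                                    values = list(score = NA_real_)))
    expect_error(disjoinAssay(na, mean, "score"), "missing value")
    expect_error(qreduceAssay(na, q, coverageWeightedMean, "score"),
                 "missing value")
})

test_that("built-in summarizers implement the documented rules", {
    expect_equal(coverageWeightedMean(5, makeRange("chr1", 1, 10),
                                      makeRange("chr1", 1, 10)), 5)
    expect_equal(coverageWeightedMean(c(2, 4),
                                      makeRange("chr1", c(1, 11), c(10, 20)),
                                      makeRange("chr1", 1, 20)), 3)

    f <- nonsilentBinary()
    expect_equal(f("Missense_Mutation", NULL, NULL), 1)
    expect_equal(f(c("Silent", "Silent"), NULL, NULL), 0)
    expect_equal(f(c("Silent", "Nonsense_Mutation"), NULL, NULL), 1)
    ## any-semantics over every subset of a 3-category vocabulary
    vocab <- c("Silent", "Missense_Mutation", "Nonsense_Mutation")
    for (n in 1:3) {
        combos <- expand.grid(rep(list(vocab), n), stringsAsFactors = FALSE)
        for (r in seq_len(nrow(combos))) {
            scores <- unlist(combos[r, ], use.names = FALSE)
            expect_equal(f(scores, NULL, NULL),
                         as.numeric(any(scores != "Silent")))
        }
    }
    g <- nonsilentBinary(c("Silent", "Intron"))
    expect_equal(g(c("Silent", "Intron"), NULL, NULL), 0)
})

test_that("reductions commute with column subsetting", {
    set.seed(161)
    q <- randomRanges(4, n.contigs = 2, L = 10000, values = FALSE)
    for (rep in 1:5) {
        ra <- generateFixture(n.samples = 4, duplicate.rate = 0.2,
                              seed = 1000 + rep)
        J <- sample(4, 3, replace = TRUE)
        expect_identical(sparseAssay(ra[, J]), sparseAssay(ra)[, J])
        expect_identical(compactAssay(ra[, J]), compactAssay(ra)[, J])
        ## disjoin fragments across *all view rows*, which column subsetting
        ## does not change
        expect_identical(disjoinAssay(ra[, J], mean),
                         disjoinAssay(ra, mean)[, J])
        expect_identical(qreduceAssay(ra[, J], q, coverageWeightedMean),
                         qreduceAssay(ra, q, coverageWeightedMean)[, J])
    }
})

test_that("assay accessors alias the sparse reduction", {
    ra <- twoSample()
    expect_equal(assayNames(ra), "score")
    expect_identical(assay(ra, "score"), sparseAssay(ra, "score"))
    expect_identical(assay(ra, 1), assay(ra, "score"))
    expect_identical(assays(ra)[["score"]], sparseAssay(ra, "score"))
    expect_error(assay(ra, "nope"), "unknown assay")
})
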