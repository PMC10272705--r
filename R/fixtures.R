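## Seeded synthetic-data generator. Every test and demo in the package runs
## on its output; no downloads. One private RNG stream per call: the global
## .Random.seed is saved and restored, so fixtures never perturb (and are
## never perturbed by) surrounding code.

.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has)
        old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Generate a synthetic ragged container
#'
#' Emulates the shapes of ragged genomic data the package targets:
#' independent per-sample ranges (mutation-like), ranges drawn from one
#' global breakpoint set per contig (guaranteeing identical ranges across
#' samples, the compact-reduction case), and per-sample non-overlapping
#' segments tiling each contig (segmented copy-number shape). Values are
#' either Gaussian (copy-number-like log ratios) or categorical (variant
#' classifications).
#'
#' Generation is fully reproducible: the same arguments and seed give an
#' identical container, and the caller's RNG state is left untouched.
#'
#' @param n.samples Number of samples (>= 0). Default 3.
#' @param ranges.per.sample Integer pair `c(lo, hi)`: per-sample range count
#'   drawn uniformly from `lo:hi`. Default `c(4, 12)`.
#' @param n.contigs Number of contigs (`chr1`, `chr2`, ...). Default 2.
#' @param contig.length Length of every contig in bases. Default 10000.
#' @param overlap.mode `"independent"`, `"shared-breakpoints"` or
#'   `"tiled"`.
#' @param value.model Either `list(dist = "normal", mean, sd)` (default
#'   mean 0, sd 1 — a centered log-ratio scale) or
#'   `list(dist = "categorical", labels, probs)` with `probs` summing to 1
#'   within 1e-9.
#' @param value.name Name of the generated metadata column; default
#'   `"score"` for normal values, `"call"` for categorical.
#' @param duplicate.rate Fraction of generated ranges additionally copied
#'   identically into another random sample (needs `n.samples >= 2`).
#'   Default 0.
#' @param seed Integer seed for the fixture's private RNG stream.
#' @return A [RaggedAssay] with a `group` phenotype column and a `Seqinfo`
#'   carrying the contig lengths.
#' @examples
#' ra <- generateFixture(n.samples = 2, seed = 1)
#' dim(ra)
#' @export
generateFixture <- function(n.samples = 3,
                            ranges.per.sample = c(4, 12),
                            n.contigs = 2,
                            contig.length = 10000,
                            overlap.mode = c("independent",
                                             "shared-breakpoints", "tiled"),
                            value.model = list(dist = "normal",
                                               mean = 0, sd = 1),
                            value.name = NULL,
                            duplicate.rate = 0,
                            seed = 0) {
    overlap.mode <- match.arg(overlap.mode)
    if (n.samples < 0 || n.contigs < 1 || contig.length < 2 ||
        length(ranges.per.sample) != 2L ||
        any(ranges.per.sample < 0) ||
        ranges.per.sample[2L] < ranges.per.sample[1L] ||
        duplicate.rate < 0 || duplicate.rate > 1)
        stop("invalid fixture specification")
    if (identical(value.model$dist, "categorical")) {
        if (abs(sum(value.model$probs) - 1) > 1e-9 ||
            length(value.model$labels) != length(value.model$probs))
            stop("invalid fixture specification: categorical probs must ",
                 "match labels and sum to 1")
    } else if (!identical(value.model$dist, "normal")) {
        stop("invalid fixture specification: unknown value model '",
             value.model$dist, "'")
    }
    if (is.null(value.name))
        value.name <- if (identical(value.model$dist, "normal")) "score"
                      else "call"
    contigs <- paste0("chr", seq_len(n.contigs))
    si <- Seqinfo(contigs, seqlengths = rep(contig.length, n.contigs))
    if (n.samples == 0)
        return(RaggedAssay(GRangesList(), seqinfo = si))

    .withSeed(seed, {
        L <- contig.length
        drawValues <- function(n) {
            if (identical(value.model$dist, "normal"))
                rnorm(n, value.model$mean, value.model$sd)
            else
                sample(value.model$labels, n, replace = TRUE,
                       prob = value.model$probs)
        }
        ## one global breakpoint set per contig for shared-breakpoints mode
        sharedBp <- lapply(contigs, function(ct)
            sort(unique(c(1L, sample(seq_len(L), 7L), L + 1L))))
        names(sharedBp) <- contigs

        parts <- lapply(seq_len(n.samples), function(s) {
            n <- if (ranges.per.sample[1L] == ranges.per.sample[2L])
                     ranges.per.sample[1L]
                 else sample(ranges.per.sample[1L]:ranges.per.sample[2L], 1L)
            if (overlap.mode == "tiled") {
                ## per-sample contiguous segmentation of every contig
                res <- lapply(contigs, function(ct) {
                    k <- max(1L, n %/% n.contigs)
                    cuts <- sort(sample(2:L, min(k - 1L, L - 2L)))
                    st <- c(1L, cuts)
                    en <- c(cuts - 1L, L)
                    data.frame(contig = ct, start = st, end = en)
                })
                df <- do.call(rbind, res)
            } else if (overlap.mode == "shared-breakpoints") {
                df <- do.call(rbind, lapply(seq_len(n), function(i) {
                    ct <- sample(contigs, 1L)
                    bp <- sharedBp[[ct]]
                    ab <- sort(sample(seq_along(bp), 2L))
                    data.frame(contig = ct, start = bp[ab[1L]],
                               end = bp[ab[2L]] - 1L)
                }))
            } else {
                ct <- sample(contigs, n, replace = TRUE)
                w <- pmax(1L, as.integer(round(stats::rexp(n, 10 / L))))
                w <- pmin(w, L)
                st <- 1L + as.integer(floor(runif(n) * (L - w + 1L)))
                df <- data.frame(contig = ct, start = st, end = st + w - 1L)
            }
            if (nrow(df) == 0L) {
                gr <- GRanges(seqinfo = si)
                mcols(gr)[[value.name]] <-
                    if (identical(value.model$dist, "normal")) numeric(0)
                    else character(0)
                return(gr)
            }
            makeRange(df$contig, df$start, df$end,
                      values = setNames(list(drawValues(nrow(df))),
                                        value.name),
                      seqinfo = si)
        })
        names(parts) <- sprintf("sample%02d", seq_len(n.samples))
        rangeKey <- function(gr)
            paste(seqnames(gr), start(gr), end(gr), strand(gr))
        ## within one sample, identical ranges must not carry conflicting
        ## values (the compact-reduction precondition): equalize duplicates
        ## to the first observation's value
        parts <- lapply(parts, function(gr) {
            key <- rangeKey(gr)
            first <- match(key, key)
            mcols(gr)[[value.name]] <- mcols(gr)[[value.name]][first]
            gr
        })
        ## copy a fraction of ranges identically into another sample that
        ## does not already observe those coordinates
        if (duplicate.rate > 0 && n.samples >= 2L) {
            origin <- parts
            moves <- do.call(rbind, lapply(seq_len(n.samples), function(s) {
                take <- which(runif(length(origin[[s]])) < duplicate.rate)
                if (!length(take))
                    return(NULL)
                others <- setdiff(seq_len(n.samples), s)
                cbind(s = s, k = take,
                      target = others[sample.int(length(others), length(take),
                                                 replace = TRUE)])
            }))
            if (!is.null(moves)) {
                for (tg in unique(moves[, "target"])) {
                    sel <- moves[moves[, "target"] == tg, , drop = FALSE]
                    extra <- do.call(c, lapply(unique(sel[, "s"]), function(s)
                        origin[[s]][sel[sel[, "s"] == s, "k"]]))
                    keep <- !duplicated(rangeKey(extra)) &
                        !rangeKey(extra) %in% rangeKey(parts[[tg]])
                    if (any(keep))
                        parts[[tg]] <- c(parts[[tg]], extra[keep])
                }
            }
        }
        coldata <- DataFrame(
            group = rep(c("A", "B"), length.out = n.samples),
            row.names = names(parts))
        RaggedAssay(GRangesList(parts, compress = TRUE),
                    colData = coldata, seqinfo = si)
    })
}
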