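# Consensus ranking: dense ranks per algorithm (tied genes share a rank, the
# next distinct metric gets the previous rank + 1) merged by the arithmetic
# mean of the three ranks, reported rounded half-up to one decimal.

# dense ranking of a metric; direction "lower" = smaller is more stable
.denseRanks <- function(metric, direction = c("lower", "higher")) {
    direction <- match.arg(direction)
    key <- if (direction == "higher") -metric else metric
    u <- sort(unique(key))
    setNames(match(key, u), names(metric))
}

# round half-up (1.666... -> 1.7, 2.05 -> 2.1); R's round() is half-to-even
.roundHalfUp <- function(x, digits = 1L) {
    p <- 10^digits
    floor(x * p + 0.5 + 1e-9) / p
}

#' Construct a per-algorithm stability report
#'
#' @param algorithm algorithm label.
#' @param metric named numeric stability metric per gene.
#' @param direction \code{"lower"} when smaller metric = more stable (geNorm
#'   M, NormFinder stability value), \code{"higher"} for BestKeeper r.
#' @param ranks optional precomputed dense ranks; computed from the metric
#'   when omitted.
#' @return A \linkS4class{StabilityReport}.
#' @export
StabilityReport <- function(algorithm, metric, direction = "lower",
                            ranks = NULL) {
    if (is.null(names(metric)))
        stop("'metric' must be named by gene")
    if (is.null(ranks))
        ranks <- .denseRanks(metric, direction)
    new("StabilityReport", algorithm = algorithm, gene = names(metric),
        metric = unname(metric), rank = as.integer(ranks[names(metric)]),
        direction = direction)
}

setMethod("show", "StabilityReport", function(object) {
    cat("StabilityReport [", object@algorithm, "], ",
        length(object@gene), " genes (", object@direction,
        " = more stable)\n", sep = "")
    ord <- order(object@rank)
    print(data.frame(gene = object@gene, metric = object@metric,
                     rank = object@rank)[ord, ], row.names = FALSE)
})

#' @rdname stabilityTable
#' @export
setMethod("stabilityTable", "StabilityReport", function(x) {
    data.frame(gene = x@gene, algorithm = x@algorithm, metric = x@metric,
               rank = x@rank)
})

#' @rdname stabilityTable
#' @export
setMethod("geneRanks", "StabilityReport", function(x) {
    setNames(x@rank, x@gene)
})

#' Assign dense ranks to stability metrics
#'
#' Genes are sorted in the stable direction; tied metrics share a rank and
#' the next distinct metric receives the previous rank + 1 (dense ranking).
#' For a lower-is-stable metric \code{c(0.2, 0.2, 0.5, 0.9)} the ranks are
#' \code{c(1, 1, 2, 3)}.
#'
#' @param x a \linkS4class{StabilityReport}, or a named numeric metric
#'   vector.
#' @param direction for numeric input: \code{"lower"} or \code{"higher"}.
#' @param unrankable policy for genes with \code{NA} metric:
#'   \code{"error"} (default) or \code{"last"} (one past the worst rank).
#' @param ... unused.
#' @return Named integer vector of dense ranks.
#' @export
setMethod("assignDenseRanks", "StabilityReport",
          function(x, unrankable = c("error", "last"), ...) {
    assignDenseRanks(setNames(x@metric, x@gene), direction = x@direction,
                     unrankable = unrankable)
})

#' @rdname assignDenseRanks
#' @export
setMethod("assignDenseRanks", "numeric",
          function(x, direction = c("lower", "higher"),
                   unrankable = c("error", "last"), ...) {
    direction <- match.arg(direction)
    unrankable <- match.arg(unrankable)
    if (is.null(names(x)))
        stop("metric vector must be named by gene")
    if (anyNA(x)) {
        if (unrankable == "error")
            stop("unrankable gene(s): ",
                 paste(names(x)[is.na(x)], collapse = ", "))
        out <- rep(NA_integer_, length(x))
        names(out) <- names(x)
        ok <- !is.na(x)
        out[ok] <- .denseRanks(x[ok], direction)
        out[!ok] <- max(out[ok], 0L) + 1L
        return(out)
    }
    .denseRanks(x, direction)
})

#' Arithmetic-mean-rank consensus of three stability rankings
#'
#' Combines geNorm, NormFinder and BestKeeper dense ranks by their arithmetic
#' mean per gene. The reported mean rank is rounded half-up to one decimal
#' (1.666... -> 1.7); full precision is kept for ordering. Consensus ties are
#' broken by geNorm rank, then input gene order.
#'
#' @param genorm,normfinder,bestkeeper per-algorithm rankings covering the
#'   same gene set: a \linkS4class{GeNormResult},
#'   \linkS4class{StabilityReport}, \linkS4class{BestKeeperResult} or a named
#'   integer rank vector.
#' @return data.frame (one row per gene, sorted most stable first):
#'   \code{gene}, \code{rankGeNorm}, \code{rankNormFinder},
#'   \code{rankBestKeeper}, \code{meanRank} (rounded, one decimal),
#'   \code{meanRankExact}.
#' @examples
#' g <- c(H2B = 1L, UBC2 = 1L, RPL2 = 2L, IDH = 3L, RCA = 4L)
#' nf <- c(IDH = 1L, RCA = 2L, UBC2 = 3L, H2B = 4L, RPL2 = 5L)
#' bk <- c(IDH = 1L, RCA = 2L, UBC2 = 3L, RPL2 = 4L, H2B = 5L)
#' meanRankConsensus(g, nf, bk)
#' @export
meanRankConsensus <- function(genorm, normfinder, bestkeeper) {
    asRanks <- function(r) {
        if (is(r, "GeNormResult") || is(r, "BestKeeperResult")) geneRanks(r)
        else if (is(r, "StabilityReport")) geneRanks(r)
        else if (is.numeric(r) && !is.null(names(r)))
            setNames(as.integer(r), names(r))
        else stop("cannot interpret a ranking argument")
    }
    rg <- asRanks(genorm); rn <- asRanks(normfinder); rb <- asRanks(bestkeeper)
    genes <- names(rg)
    for (r in list(rn, rb)) {
        miss <- union(setdiff(genes, names(r)), setdiff(names(r), genes))
        if (length(miss))
            stop("gene(s) missing from one of the rankings: ",
                 paste(miss, collapse = ", "))
    }
    if (anyNA(rg[genes]) || anyNA(rn[genes]) || anyNA(rb[genes]))
        stop("all genes must carry a rank in every algorithm")
    mr <- (rg[genes] + rn[genes] + rb[genes]) / 3
    out <- data.frame(gene = genes,
                      rankGeNorm = unname(rg[genes]),
                      rankNormFinder = unname(rn[genes]),
                      rankBestKeeper = unname(rb[genes]),
                      meanRank = .roundHalfUp(unname(mr), 1L),
                      meanRankExact = unname(mr))
    out[order(out$meanRankExact, out$rankGeNorm, seq_len(nrow(out))), ,
        drop = FALSE]
}
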