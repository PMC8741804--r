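# BestKeeper: per-gene descriptive statistics of Ct and the correlation of
# each gene with the BestKeeper index (per-sample geometric mean Ct of all
# candidate genes). Genes with higher r are more stable.

#' BestKeeper descriptive statistics and index correlation
#'
#' Computes, per gene and on the Ct scale: geometric mean, arithmetic mean,
#' minimum, maximum, SD, CV (\eqn{100 \cdot SD / AM}) and the Pearson
#' correlation r of the gene's Ct with the BestKeeper index. Genes are ranked
#' by descending r. A gene with zero Ct variance has undefined r and is
#' reported as not rankable.
#'
#' @param x a \linkS4class{CtExperiment} or numeric Ct matrix (>= 2 samples,
#'   complete).
#' @param sdMethod \code{"sd"}: classical sample standard deviation of Ct
#'   (default, matching a "standard deviation" column); \code{"mad_gm"}: mean
#'   absolute deviation from the geometric mean, the original tool's
#'   dispersion measure.
#' @return A \linkS4class{BestKeeperResult}.
#' @export
bestKeeper <- function(x, sdMethod = c("sd", "mad_gm")) {
    sdMethod <- match.arg(sdMethod)
    m <- .asCtMatrix(x)
    if (ncol(m) < 2L)
        stop("BestKeeper needs >= 2 samples")
    gm <- exp(rowMeans(log(m)))
    am <- rowMeans(m)
    sdv <- switch(sdMethod,
                  sd = apply(m, 1L, stats::sd),
                  mad_gm = rowMeans(abs(m - gm)))
    cv <- 100 * sdv / am
    index <- exp(colMeans(log(m)))
    ctsd <- apply(m, 1L, stats::sd)
    r <- rep(NA_real_, nrow(m))
    ok <- ctsd > 0 & stats::sd(index) > 0
    r[ok] <- apply(m[ok, , drop = FALSE], 1L, stats::cor, y = index)
    undefined <- rownames(m)[!ok]
    ranks <- rep(NA_integer_, nrow(m))
    if (any(ok))
        ranks[ok] <- .denseRanks(r[ok], direction = "higher")
    stats <- data.frame(gene = rownames(m), geoMean = gm, ariMean = am,
                        min = apply(m, 1L, min), max = apply(m, 1L, max),
                        sd = sdv, cv = cv, r = r, row.names = NULL)
    new("BestKeeperResult", stats = stats,
        index = setNames(index, colnames(m)),
        ranks = setNames(ranks, rownames(m)), undefined = undefined,
        sdMethod = sdMethod)
}

setMethod("show", "BestKeeperResult", function(object) {
    cat("BestKeeperResult:", nrow(object@stats), "genes,",
        length(object@index), "samples (SD method:", object@sdMethod, ")\n")
    print(object@stats, digits = 4)
    if (length(object@undefined))
        cat("  r undefined (zero Ct variance):",
            paste(object@undefined, collapse = ", "), "\n")
})

#' @rdname stabilityTable
#' @export
setMethod("geneRanks", "BestKeeperResult", function(x) x@ranks)

#' @rdname stabilityTable
#' @export
setMethod("stabilityTable", "BestKeeperResult", function(x) {
    data.frame(gene = x@stats$gene, algorithm = "BestKeeper",
               metric = x@stats$r, rank = unname(x@ranks))
})
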