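# Expression-table analyses around the stability pipeline: screening of
# candidate reference genes from FPKM tables, per-gene z-score
# standardization, K-means expression clustering (k-means++ seeding, Lloyd
# iterations) and a pairwise fold-change / p-value differential expression
# filter.

.exprMatrix <- function(x) {
    if (is(x, "FPKMExperiment")) exprValues(x)
    else if (is.matrix(x) && is.numeric(x)) x
    else stop("expected an FPKMExperiment or a numeric matrix")
}

.tissueValues <- function(x) {
    m <- .exprMatrix(x)
    groups <- if (is(x, "FPKMExperiment")) sampleGroups(x) else NULL
    if (is.null(groups)) return(m)
    glev <- levels(groups)
    out <- vapply(glev, function(g)
        rowMeans(m[, groups == g, drop = FALSE]), numeric(nrow(m)))
    matrix(out, nrow(m), length(glev), dimnames = list(rownames(m), glev))
}

#' Screen candidate reference genes from an expression table
#'
#' Retains genes that are (i) expressed at or above \code{minFPKM} in every
#' tissue, (ii) flat across tissues: the largest pairwise fold change between
#' tissue values is below \code{maxFold}, and (iii) non-significant in every
#' differential comparison: all q-values at or above \code{minQ}. When the
#' table carries group labels, tissue values are group means of FPKM;
#' otherwise each column is treated as one tissue.
#'
#' @param x an \linkS4class{FPKMExperiment} or numeric matrix.
#' @param qvalues genes x comparisons matrix of q-values (rownames must cover
#'   the genes of \code{x}).
#' @param minFPKM minimum abundance in every tissue (default 5).
#' @param maxFold upper fold-change bound, exclusive (default 2).
#' @param minQ minimum q-value, inclusive (default 0.05).
#' @return Character vector of retained candidate reference genes, in input
#'   order.
#' @export
screenCandidateReferences <- function(x, qvalues, minFPKM = 5, maxFold = 2,
                                      minQ = 0.05) {
    tv <- .tissueValues(x)
    if (is.null(rownames(qvalues)) ||
        !all(rownames(tv) %in% rownames(qvalues)))
        stop("q-values missing for some genes")
    q <- qvalues[rownames(tv), , drop = FALSE]
    if (anyNA(q))
        stop("q-values contain missing entries")
    expressed <- apply(tv >= minFPKM, 1L, all)
    maxfc <- apply(tv, 1L, function(v) max(v) / min(v))
    flat <- maxfc < maxFold
    nonsig <- apply(q >= minQ, 1L, all)
    rownames(tv)[expressed & flat & nonsig]
}

#' Per-gene z-score standardization
#'
#' Centers and scales each gene row to mean 0 and SD 1. Zero-variance rows
#' are mapped to all zeros and flagged in the \code{"constant"} attribute.
#'
#' @param x an \linkS4class{FPKMExperiment} or numeric matrix (>= 2 samples).
#' @param sdType \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"} (n denominator).
#' @return Standardized matrix with attribute \code{"constant"} (logical per
#'   gene).
#' @export
zscoreStandardize <- function(x, sdType = c("sample", "population")) {
    sdType <- match.arg(sdType)
    m <- .exprMatrix(x)
    if (ncol(m) < 2L)
        stop("z-score standardization needs >= 2 samples")
    mu <- rowMeans(m)
    s <- apply(m, 1L, stats::sd)
    if (sdType == "population")
        s <- s * sqrt((ncol(m) - 1) / ncol(m))
    const <- s == 0
    s[const] <- 1
    z <- (m - mu) / s
    z[const, ] <- 0
    attr(z, "constant") <- setNames(const, rownames(m))
    z
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then each
# new center drawn with probability proportional to squared distance to the
# nearest chosen center.
.kmeansppCenters <- function(m, k) {
    n <- nrow(m)
    centers <- integer(k)
    centers[1L] <- sample.int(n, 1L)
    d2 <- rowSums((m - matrix(m[centers[1L], ], n, ncol(m),
                              byrow = TRUE))^2)
    for (i in seq_len(k - 1L) + 1L) {
        if (all(d2 == 0)) {
            centers[i] <- sample.int(n, 1L)
        } else {
            centers[i] <- sample.int(n, 1L, prob = d2)
        }
        nd <- rowSums((m - matrix(m[centers[i], ], n, ncol(m),
                                  byrow = TRUE))^2)
        d2 <- pmin(d2, nd)
    }
    m[centers, , drop = FALSE]
}

#' K-means clustering of expression profiles
#'
#' Lloyd's algorithm started from k-means++ seeds; the best of
#' \code{nRestarts} runs by total within-cluster sum of squares (inertia) is
#' returned. Deterministic for a fixed seed.
#'
#' @param x standardized genes x samples matrix (see [zscoreStandardize()]),
#'   or an \linkS4class{FPKMExperiment}.
#' @param k number of clusters (<= number of genes).
#' @param seed RNG seed (required).
#' @param nRestarts number of independent seedings (default 10).
#' @return A \linkS4class{ClusterResult}.
#' @export
kmeansCluster <- function(x, k, seed, nRestarts = 10L) {
    m <- .exprMatrix(x)
    if (k > nrow(m))
        stop("k must not exceed the number of genes")
    if (missing(seed))
        stop("'seed' is required for reproducible clustering")
    best <- withr::with_seed(as.integer(seed), {
        res <- NULL
        for (i in seq_len(nRestarts)) {
            init <- .kmeansppCenters(m, k)
            km <- suppressWarnings(
                stats::kmeans(m, centers = init, iter.max = 100L,
                              algorithm = "Lloyd"))
            if (is.null(res) || km$tot.withinss < res$tot.withinss)
                res <- km
        }
        res
    })
    new("ClusterResult",
        cluster = setNames(as.integer(best$cluster), rownames(m)),
        centers = best$centers, k = as.integer(k),
        seed = as.integer(seed), inertia = best$tot.withinss,
        restarts = as.integer(nRestarts))
}

setMethod("show", "ClusterResult", function(object) {
    cat("ClusterResult: k =", object@k, "clusters over",
        length(object@cluster), "genes; inertia",
        format(object@inertia, digits = 5), "(best of", object@restarts,
        "restarts, seed", paste0(object@seed, ")"), "\n")
    print(table(cluster = object@cluster))
})

#' Cluster assignments
#'
#' @param x a \linkS4class{ClusterResult}.
#' @return Named integer vector of cluster ids.
#' @export
clusterAssignments <- function(x) x@cluster

#' Pairwise differential expression filter
#'
#' Enumerates all pairwise group comparisons (6 for 4 tissues). Per gene and
#' comparison: linear-scale fold change = ratio of group means,
#' direction-agnostic (\eqn{\max(ratio, 1/ratio)}); p value from a two-sided
#' Welch t-test on log2 values. A gene x comparison passes when the fold
#' change exceeds \code{foldThreshold} in either direction and p <
#' \code{pThreshold}. A one-way ANOVA p value per gene over all groups is
#' reported as an overall statistic.
#'
#' @param x an \linkS4class{FPKMExperiment} (positive values) or numeric
#'   matrix.
#' @param groups group labels per sample; defaults to the labels stored in
#'   \code{x}.
#' @param foldThreshold linear fold-change threshold, exclusive (default 2).
#' @param pThreshold p-value threshold, exclusive (default 0.05).
#' @param adjust p adjustment across genes within each comparison
#'   (\code{"none"} default, or any [stats::p.adjust()] method such as
#'   \code{"BH"}).
#' @param strict require >= 2 replicates in every group (error otherwise);
#'   when \code{FALSE}, comparisons without replication report fold change
#'   only (p = NA, pass = NA).
#' @return A list: \code{table} — data.frame (gene, comparison, foldChange,
#'   log2FoldChange, p, pass); \code{anova} — named per-gene one-way ANOVA p;
#'   \code{comparisons} — the comparison labels.
#' @export
differentialExpressionFilter <- function(x, groups = NULL,
                                         foldThreshold = 2,
                                         pThreshold = 0.05,
                                         adjust = "none", strict = TRUE) {
    m <- .exprMatrix(x)
    if (is.null(groups) && is(x, "FPKMExperiment"))
        groups <- sampleGroups(x)
    if (is.null(groups))
        stop("group labels are required")
    if (!is.null(names(groups))) groups <- groups[colnames(m)]
    groups <- factor(as.character(groups))
    if (nlevels(groups) < 2L)
        stop("need >= 2 groups")
    if (any(m <= 0))
        stop("differential expression testing needs positive values ",
             "(log2 scale)")
    sizes <- table(groups)
    if (strict && any(sizes < 2L))
        stop("every group needs >= 2 replicates for p values; ",
             "offending group(s): ",
             paste(names(sizes)[sizes < 2L], collapse = ", "))
    lev <- levels(groups)
    prs <- utils::combn(lev, 2L)
    comparisons <- paste(prs[1L, ], prs[2L, ], sep = "_vs_")
    lm2 <- log2(m)
    rows <- vector("list", ncol(prs))
    for (ci in seq_len(ncol(prs))) {
        i1 <- groups == prs[1L, ci]; i2 <- groups == prs[2L, ci]
        mu1 <- rowMeans(m[, i1, drop = FALSE])
        mu2 <- rowMeans(m[, i2, drop = FALSE])
        fc <- mu1 / mu2
        fcdir <- pmax(fc, 1 / fc)
        p <- rep(NA_real_, nrow(m))
        if (sum(i1) >= 2L && sum(i2) >= 2L) {
            p <- vapply(seq_len(nrow(m)), function(g) {
                a <- lm2[g, i1]; b <- lm2[g, i2]
                if (stats::sd(a) == 0 && stats::sd(b) == 0)
                    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
                stats::t.test(a, b)$p.value
            }, numeric(1))
        }
        p <- stats::p.adjust(p, method = adjust)
        rows[[ci]] <- data.frame(gene = rownames(m),
                                 comparison = comparisons[ci],
                                 foldChange = unname(fcdir),
                                 log2FoldChange = unname(log2(fc)),
                                 p = unname(p),
                                 pass = unname(fcdir > foldThreshold &
                                               !is.na(p) & p < pThreshold))
        if (anyNA(p))
            rows[[ci]]$pass[is.na(p)] <- NA
    }
    av <- vapply(seq_len(nrow(m)), function(g) {
        if (all(sizes >= 2L))
            stats::oneway.test(lm2[g, ] ~ groups, var.equal = TRUE)$p.value
        else NA_real_
    }, numeric(1))
    list(table = do.call(rbind, rows), anova = setNames(av, rownames(m)),
         comparisons = comparisons)
}
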