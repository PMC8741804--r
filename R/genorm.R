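# geNorm: gene-stability measure M (mean pairwise variation of log ratios)
# and the stepwise-exclusion ranking with pairwise variation V(n/n+1) between
# normalization factors. Operates on relative quantities
# Q_ij = (1 + E_i/100)^(Ctmin_i - Ct_ij); by default E = 100% so Q = 2^dCt.

.asCtMatrix <- function(x) {
    if (is(x, "CtExperiment")) ctValues(x)
    else if (is.matrix(x) && is.numeric(x)) x
    else stop("expected a CtExperiment or a numeric matrix")
}

# log2 relative quantities per gene (rows)
.log2Quantities <- function(m, efficiency = NULL) {
    if (is.null(efficiency)) {
        e <- rep(2, nrow(m))
    } else {
        eff <- if (!is.null(names(efficiency)))
            efficiency[rownames(m)] else rep_len(efficiency, nrow(m))
        if (anyNA(eff) || any(eff <= 0))
            stop("efficiencies must be positive and cover every gene")
        e <- 1 + eff / 100
    }
    log2(e) * (apply(m, 1L, min) - m)
}

#' geNorm M values
#'
#' For each pair of genes the pairwise variation V_jk is the standard
#' deviation over samples of the log2 ratio of their relative quantities; the
#' M value of a gene is the arithmetic mean of its V_jk against all other
#' genes. Lower M = more stable. M is invariant under per-sample additive Ct
#' shifts (common variation).
#'
#' @param x a \linkS4class{CtExperiment} (complete, no replicate dimension
#'   needed; replicates are averaged) or a numeric Ct matrix.
#' @param efficiency optional per-gene amplification efficiency in percent
#'   (named vector or scalar); default 100\% for every gene, i.e.
#'   \eqn{Q = 2^{Ct_{min} - Ct}}.
#' @return Named numeric vector of M values.
#' @export
geNormM <- function(x, efficiency = NULL) {
    m <- .asCtMatrix(x)
    if (nrow(m) < 2L)
        stop("geNorm needs >= 2 genes")
    if (nrow(m) == 2L)
        warning("only 2 genes: M equals the pairwise variation V for both")
    if (ncol(m) < 2L)
        stop("geNorm needs >= 2 samples")
    l <- .log2Quantities(m, efficiency)
    n <- nrow(l)
    V <- matrix(0, n, n)
    for (j in seq_len(n - 1L)) {
        for (k in (j + 1L):n) {
            V[j, k] <- V[k, j] <- stats::sd(l[j, ] - l[k, ])
        }
    }
    setNames(rowSums(V) / (n - 1L), rownames(m))
}

#' geNorm stepwise-exclusion ranking
#'
#' Iteratively removes the gene with the highest M and recomputes M on the
#' remainder. The final two genes cannot be ranked against each other and
#' share rank 1. The pairwise variation V(n/n+1) is the SD over samples of
#' the log2 ratio of normalization factors (per-sample geometric means of the
#' n and n+1 most stable genes); the smallest n with V(n/n+1) below
#' \code{vCutoff} is the recommended number of references.
#'
#' @inheritParams geNormM
#' @param vCutoff pairwise-variation cutoff for the recommended reference
#'   count (conventional 0.15).
#' @return A \linkS4class{GeNormResult}.
#' @export
geNormRanking <- function(x, efficiency = NULL, vCutoff = 0.15) {
    m <- .asCtMatrix(x)
    if (nrow(m) < 3L)
        stop("stepwise geNorm ranking needs >= 3 genes")
    genes <- rownames(m)
    remaining <- genes
    exclusion <- character(0)
    finalM <- setNames(numeric(length(genes)), genes)
    while (length(remaining) > 2L) {
        M <- geNormM(m[remaining, , drop = FALSE], efficiency)
        worst <- which(M == max(M))
        worst <- worst[length(worst)]        # tie: drop the later input gene
        g <- remaining[worst]
        finalM[g] <- M[worst]
        exclusion <- c(exclusion, g)
        remaining <- setdiff(remaining, g)
    }
    lastM <- suppressWarnings(geNormM(m[remaining, , drop = FALSE],
                                      efficiency))
    finalM[remaining] <- lastM
    stab <- c(remaining, rev(exclusion))     # most stable first
    ranks <- setNames(c(1L, 1L, seq_len(length(stab) - 2L) + 1L), stab)[genes]
    # V(n/n+1) between normalization factors of the n/n+1 most stable genes
    l <- .log2Quantities(m, efficiency)
    pv <- numeric(0)
    if (length(stab) > 2L) {
        pv <- vapply(2:(length(stab) - 1L), function(n) {
            nf.n <- colMeans(l[stab[seq_len(n)], , drop = FALSE])
            nf.n1 <- colMeans(l[stab[seq_len(n + 1L)], , drop = FALSE])
            stats::sd(nf.n - nf.n1)
        }, numeric(1))
        names(pv) <- paste0("V", 2:(length(stab) - 1L), "/",
                            3:length(stab))
    }
    recN <- if (length(pv) && any(pv < vCutoff))
        as.integer(1L + which(pv < vCutoff)[1L]) else NA_integer_
    new("GeNormResult", M = finalM, exclusionOrder = exclusion,
        ranks = ranks, pairwiseVariation = pv, recommendedN = recN,
        vCutoff = vCutoff)
}

setMethod("show", "GeNormResult", function(object) {
    ord <- names(sort(object@ranks))
    cat("GeNormResult:", length(object@M), "genes\n")
    cat("  stability (most stable first):", paste(ord, collapse = ", "), "\n")
    if (length(object@pairwiseVariation))
        cat("  V(n/n+1):",
            paste(sprintf("%s=%.3f", names(object@pairwiseVariation),
                          object@pairwiseVariation), collapse = "  "), "\n")
    cat("  recommended references:",
        if (is.na(object@recommendedN)) "none below cutoff"
        else object@recommendedN, "\n")
})

#' @rdname stabilityTable
#' @export
setMethod("geneRanks", "GeNormResult", function(x) x@ranks)

#' Tidy per-gene stability tables and ranks
#'
#' \code{stabilityTable} returns a data.frame (gene, metric, rank);
#' \code{geneRanks} the named integer rank vector (1 = most stable).
#'
#' @param x a \linkS4class{GeNormResult}, \linkS4class{StabilityReport} or
#'   \linkS4class{BestKeeperResult}.
#' @return data.frame or named integer vector.
#' @export
setMethod("stabilityTable", "GeNormResult", function(x) {
    data.frame(gene = names(x@M), algorithm = "geNorm",
               metric = unname(x@M), rank = unname(x@ranks))
})
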