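# Relative quantification by 2^-ddCt against a multi-reference normalization
# factor. The per-sample reference factor is the arithmetic mean of the
# reference genes' Ct, which under a common efficiency equals (on the
# quantity scale) the geometric mean of the reference quantities:
# 2^-mean(Ct) = geomean(2^-Ct). Efficiency is fixed at 100% (one cycle = one
# twofold change).

#' Per-sample reference normalization factor
#'
#' Arithmetic mean Ct of the reference genes per sample; equivalently, on the
#' quantity scale, the geometric mean of the reference genes' relative
#' quantities.
#'
#' @param x a \linkS4class{CtExperiment} or numeric Ct matrix.
#' @param refs non-empty character vector of reference genes.
#' @return Named numeric vector, one reference Ct per sample.
#' @export
referenceFactor <- function(x, refs) {
    m <- .asCtMatrix(x)
    if (length(refs) == 0L)
        stop("the reference gene set must not be empty")
    miss <- setdiff(refs, rownames(m))
    if (length(miss))
        stop("reference gene(s) not in the matrix: ",
             paste(miss, collapse = ", "))
    colMeans(m[refs, , drop = FALSE])
}

#' Relative expression by 2^-ddCt
#'
#' For each target gene, \eqn{\Delta Ct = Ct_{target} - } reference factor per
#' sample, \eqn{\Delta\Delta Ct = \Delta Ct - \Delta Ct_{calibrator}} and
#' fold change \eqn{2^{-\Delta\Delta Ct}}. The calibrator is a sample (its
#' own \eqn{\Delta Ct}) or a group label (arithmetic mean \eqn{\Delta Ct}
#' over the group's samples). Fold change is 1 at the calibrator sample by
#' construction, and all fold changes are invariant to per-sample additive Ct
#' shifts (loading differences).
#'
#' @param x a \linkS4class{CtExperiment} (group labels required for a group
#'   calibrator) or numeric Ct matrix.
#' @param targets one or more target genes (must not overlap \code{refs}).
#' @param refs reference gene set for the normalization factor.
#' @param calibrator a sample identifier or a group label.
#' @return A \linkS4class{RelativeExpression}.
#' @export
deltaDeltaCt <- function(x, targets, refs, calibrator) {
    m <- .asCtMatrix(x)
    if (any(targets %in% refs))
        stop("target gene(s) must not be part of the reference set: ",
             paste(intersect(targets, refs), collapse = ", "))
    miss <- setdiff(targets, rownames(m))
    if (length(miss))
        stop("target gene(s) not in the matrix: ",
             paste(miss, collapse = ", "))
    rf <- referenceFactor(m, refs)
    groups <- if (is(x, "CtExperiment")) sampleGroups(x) else NULL
    if (calibrator %in% colnames(m)) {
        type <- "sample"
        calIdx <- which(colnames(m) == calibrator)
    } else if (!is.null(groups) && calibrator %in% as.character(groups)) {
        type <- "group"
        calIdx <- which(as.character(groups) == calibrator)
    } else {
        stop("calibrator '", calibrator,
             "' is neither a sample nor a group label")
    }
    tab <- do.call(rbind, lapply(targets, function(tg) {
        dct <- m[tg, ] - rf
        ddct <- dct - mean(dct[calIdx])
        data.frame(target = tg, sample = colnames(m), dCt = unname(dct),
                   ddCt = unname(ddct), foldChange = 2^(-unname(ddct)))
    }))
    rownames(tab) <- NULL
    new("RelativeExpression", table = tab, refs = refs,
        calibrator = calibrator, calibratorType = type)
}

setMethod("show", "RelativeExpression", function(object) {
    cat("RelativeExpression: 2^-ddCt,",
        length(unique(object@table$target)), "target(s) normalized to {",
        paste(object@refs, collapse = ", "), "}, calibrator ",
        object@calibratorType, " '", object@calibrator, "'\n", sep = "")
    print(utils::head(object@table, 10L), row.names = FALSE)
    if (nrow(object@table) > 10L) cat("...\n")
})

#' Fold changes of a RelativeExpression as a matrix
#'
#' @param x a \linkS4class{RelativeExpression}.
#' @return targets x samples matrix of 2^-ddCt fold changes.
#' @export
foldChanges <- function(x) {
    stopifnot(is(x, "RelativeExpression"))
    tg <- unique(x@table$target)
    sm <- unique(x@table$sample)
    out <- matrix(NA_real_, length(tg), length(sm),
                  dimnames = list(tg, sm))
    out[cbind(x@table$target, x@table$sample)] <- x@table$foldChange
    out
}
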