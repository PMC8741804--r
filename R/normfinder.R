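# NormFinder-style variance decomposition. On log2 quantities (negated Ct,
# perfect-doubling scale) the model per group is
#   y_igj = alpha_ig + beta_gj + e_igj,  Var(e) = sigma^2_ig.
# Two-way centering within each group yields residuals whose scaled sums of
# squares give a moment-corrected intra-group variance estimate; inter-group
# deviations d_ig are shrunk toward 0 by their sampling variance. The
# stability value is the mean over groups of |shrunken d_ig| plus the mean
# intra-group SD; lower = more stable. Ungrouped mode returns the model-based
# per-gene SD alone.

# moment-corrected per-gene variance from two-way residuals of one group
.nfGroupVariance <- function(sub) {
    z <- nrow(sub); n <- ncol(sub)
    r <- sub - rowMeans(sub) -
        matrix(colMeans(sub), z, n, byrow = TRUE) + mean(sub)
    s2 <- rowSums(r^2) / (n - 1L)
    (z / (z - 2L)) * (s2 - mean(s2) / (z - 1L))
}

#' NormFinder stability values
#'
#' Estimates, per gene, the intra-group expression variance and (when group
#' labels are available) the inter-group deviation, and combines them into a
#' single stability value; lower values indicate more stable expression.
#' Grouped mode requires >= 2 groups with >= 2 samples each; ungrouped mode
#' (>= 3 samples) reports the model-based per-gene variation only. Negative
#' moment-corrected variance estimates are clamped to 0 and flagged.
#'
#' @param x a \linkS4class{CtExperiment} or numeric Ct matrix (>= 3 genes,
#'   complete).
#' @param groups group labels per sample (named vector or factor in column
#'   order); defaults to the group labels stored in \code{x}. Pass
#'   \code{NULL} with \code{grouped = FALSE} to force ungrouped mode.
#' @param grouped use the grouped model when labels are available.
#' @param details return diagnostics alongside the report.
#' @return A \linkS4class{StabilityReport} (direction "lower"), or when
#'   \code{details = TRUE} a list with the report, per-group intra-group
#'   variances, raw and shrunken inter-group deviations and the genes whose
#'   variance was clamped at zero.
#' @export
normFinder <- function(x, groups = NULL, grouped = TRUE, details = FALSE) {
    m <- .asCtMatrix(x)
    if (nrow(m) < 3L)
        stop("NormFinder needs >= 3 genes")
    if (is.null(groups) && is(x, "CtExperiment"))
        groups <- sampleGroups(x)
    y <- -m                                  # log2 quantity scale (E = 100%)
    z <- nrow(y)
    clamped <- character(0)
    if (grouped && !is.null(groups)) {
        if (!is.null(names(groups))) groups <- groups[colnames(m)]
        groups <- factor(as.character(groups))
        if (nlevels(groups) < 2L)
            stop("grouped NormFinder needs >= 2 groups")
        sizes <- table(groups)
        if (any(sizes < 2L))
            stop("every group needs >= 2 samples; offending group(s): ",
                 paste(names(sizes)[sizes < 2L], collapse = ", "))
        G <- nlevels(groups)
        sigma2 <- matrix(NA_real_, z, G,
                         dimnames = list(rownames(y), levels(groups)))
        ybar <- sigma2
        for (g in levels(groups)) {
            sub <- y[, groups == g, drop = FALSE]
            v <- .nfGroupVariance(sub)
            if (any(v < 0))
                clamped <- union(clamped, rownames(y)[v < 0])
            sigma2[, g] <- pmax(v, 0)
            ybar[, g] <- rowMeans(sub)
        }
        d <- ybar - rowMeans(ybar) -
            matrix(colMeans(ybar), z, G, byrow = TRUE) + mean(ybar)
        vd <- sweep(sigma2, 2L, as.numeric(sizes[colnames(sigma2)]), "/")
        gamma2 <- max(0, sum(d^2) / ((z - 1L) * (G - 1L)) - mean(vd))
        shrink <- gamma2 / (gamma2 + vd)
        shrink[gamma2 + vd == 0] <- 0       # no signal and no noise estimate
        dshr <- d * shrink
        stab <- rowMeans(abs(dshr)) + rowMeans(sqrt(sigma2))
    } else {
        if (ncol(y) < 3L)
            stop("ungrouped NormFinder needs >= 3 samples")
        v <- .nfGroupVariance(y)
        if (any(v < 0)) clamped <- rownames(y)[v < 0]
        sigma2 <- matrix(pmax(v, 0), ncol = 1L,
                         dimnames = list(rownames(y), "all"))
        d <- dshr <- NULL
        stab <- sqrt(sigma2[, 1L])
    }
    names(stab) <- rownames(m)
    if (length(clamped))
        message("negative variance estimate clamped to 0 for: ",
                paste(clamped, collapse = ", "))
    rep <- StabilityReport("NormFinder", stab, direction = "lower")
    if (!details) return(rep)
    list(report = rep, intraGroupVariance = sigma2, interGroupDeviation = d,
         shrunkenDeviation = dshr, clamped = clamped)
}
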