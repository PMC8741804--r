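# Central data containers. CtExperiment and FPKMExperiment extend
# SummarizedExperiment: genes in rows, samples in columns, optional tissue
# group labels in colData. Technical replicates of a CtExperiment are held as
# a 3-dimensional assay (gene x sample x replicate) until collapsed.

.validCt <- function(object) {
    msg <- character()
    if (!("ct" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'ct' is required")
    else {
        a <- SummarizedExperiment::assay(object, "ct")
        if (is.null(rownames(object)) || is.null(colnames(object)))
            msg <- c(msg, "gene (row) and sample (column) names are required")
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, "duplicate gene identifiers")
        if (anyDuplicated(colnames(object)))
            msg <- c(msg, "duplicate sample identifiers")
        if (length(dim(a)) == 3L) {
            ok.cell <- apply(!is.na(a), c(1L, 2L), sum) >= 1L
            if (!all(ok.cell))
                msg <- c(msg, "every gene x sample cell needs >= 1 replicate")
            v <- a[!is.na(a)]
            if (!all(is.finite(v) & v > 0))
                msg <- c(msg, "all Ct values must be finite and > 0")
        } else {
            if (!all(is.finite(a) & a > 0))
                msg <- c(msg, "all Ct values must be finite and > 0")
        }
        if ("group" %in% colnames(SummarizedExperiment::colData(object))) {
            g <- SummarizedExperiment::colData(object)$group
            if (anyNA(g))
                msg <- c(msg, "every sample must carry exactly one group label")
        }
    }
    if (length(msg)) msg else TRUE
}

#' Ct matrix container
#'
#' Holds quantification-cycle (Ct) values, genes in rows and samples in
#' columns, as a \linkS4class{SummarizedExperiment} with assay \code{"ct"}.
#' Technical replicates may be supplied as a 3-d array (gene x sample x
#' replicate, ragged cells padded with \code{NA}); [collapseReplicates()]
#' reduces them to the per-cell mean. Optional tissue/group labels live in
#' \code{colData(x)$group}.
#'
#' @export
setClass("CtExperiment", contains = "SummarizedExperiment", validity = .validCt)

.validFPKM <- function(object) {
    msg <- character()
    if (!("expr" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'expr' is required")
    else {
        a <- SummarizedExperiment::assay(object, "expr")
        if (!all(is.finite(a) & a >= 0))
            msg <- c(msg, "all expression values must be finite and >= 0")
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, "duplicate gene identifiers")
        if (anyDuplicated(colnames(object)))
            msg <- c(msg, "duplicate sample identifiers")
    }
    if (length(msg)) msg else TRUE
}

#' Abundance matrix container (FPKM or relative expression)
#'
#' Non-negative abundance values (FPKM or relative expression), genes in rows
#' and samples/tissues in columns, assay \code{"expr"}; optional group labels
#' in \code{colData(x)$group}.
#'
#' @export
setClass("FPKMExperiment", contains = "SummarizedExperiment",
         validity = .validFPKM)

#' Dilution series for a standard curve
#'
#' One gene's serial-dilution calibration points: \code{log10Quantity} is the
#' log10 relative template input (fivefold series by convention, most
#' concentrated point at 0), \code{ct} the measured Ct per point.
#'
#' @slot gene gene identifier.
#' @slot log10Quantity numeric, strictly monotone, length >= 3.
#' @slot ct numeric Ct per point, finite.
#' @export
setClass("DilutionSeries",
         representation(gene = "character", log10Quantity = "numeric",
                        ct = "numeric"),
         validity = function(object) {
             msg <- character()
             if (length(object@log10Quantity) < 3L)
                 msg <- c(msg, "a dilution series needs >= 3 points")
             if (length(object@ct) != length(object@log10Quantity))
                 msg <- c(msg, "ct and log10Quantity lengths differ")
             d <- diff(object@log10Quantity)
             if (length(d) && !(all(d > 0) || all(d < 0)))
                 msg <- c(msg, "log10Quantity must be strictly monotone")
             if (!all(is.finite(object@ct)))
                 msg <- c(msg, "Ct values must be finite")
             if (length(msg)) msg else TRUE
         })

#' Fitted standard curve
#'
#' @slot gene gene identifier.
#' @slot slope cycles per log10 quantity (negative for a valid assay).
#' @slot intercept cycles at log10 quantity 0.
#' @slot rSquared squared Pearson correlation of the fit.
#' @slot efficiency amplification efficiency in percent,
#'   \eqn{E = (10^{-1/slope} - 1) \times 100}; \code{NA} when flagged invalid.
#' @slot valid FALSE when the slope is non-negative (efficiency undefined).
#' @slot n number of dilution points used.
#' @export
setClass("StandardCurveFit",
         representation(gene = "character", slope = "numeric",
                        intercept = "numeric", rSquared = "numeric",
                        efficiency = "numeric", valid = "logical",
                        n = "integer"))

#' Per-gene stability metrics and ranks for one algorithm
#'
#' @slot algorithm "geNorm", "NormFinder" or "BestKeeper" (free text allowed).
#' @slot gene gene identifiers.
#' @slot metric stability metric (M, stability value, or Pearson r).
#' @slot rank dense rank per gene, 1 = most stable; \code{NA} = unrankable.
#' @slot direction "lower" if smaller metric means more stable, else "higher".
#' @export
setClass("StabilityReport",
         representation(algorithm = "character", gene = "character",
                        metric = "numeric", rank = "integer",
                        direction = "character"),
         validity = function(object) {
             msg <- character()
             n <- length(object@gene)
             if (length(object@metric) != n || length(object@rank) != n)
                 msg <- c(msg, "gene, metric and rank lengths differ")
             if (anyDuplicated(object@gene))
                 msg <- c(msg, "duplicate gene identifiers")
             if (!object@direction %in% c("lower", "higher"))
                 msg <- c(msg, "direction must be 'lower' or 'higher'")
             if (length(msg)) msg else TRUE
         })

#' geNorm stepwise-exclusion result
#'
#' @slot M final M value per gene (the M at the step the gene was excluded;
#'   the last two genes share the M of the final pair).
#' @slot exclusionOrder genes in order of removal (least stable first).
#' @slot ranks dense ranks, final two genes tied at rank 1.
#' @slot pairwiseVariation V(n/n+1) between normalization factors of the n and
#'   n+1 most stable genes, names "V2/3", "V3/4", ...
#' @slot recommendedN smallest n with V(n/n+1) below \code{vCutoff}
#'   (\code{NA} when no n qualifies).
#' @slot vCutoff pairwise-variation cutoff used (default 0.15).
#' @export
setClass("GeNormResult",
         representation(M = "numeric", exclusionOrder = "character",
                        ranks = "integer", pairwiseVariation = "numeric",
                        recommendedN = "integer", vCutoff = "numeric"))

#' BestKeeper descriptive statistics and index correlations
#'
#' @slot stats data.frame per gene: geometric mean, arithmetic mean, min, max,
#'   SD, CV (percent) of Ct, and Pearson r against the BestKeeper index.
#' @slot index per-sample geometric mean Ct over all candidate genes.
#' @slot ranks dense ranks by descending r; \code{NA} for unrankable genes.
#' @slot undefined genes whose r is undefined (zero Ct variance).
#' @slot sdMethod "sd" (sample standard deviation) or "mad_gm" (mean absolute
#'   deviation from the geometric mean).
#' @export
setClass("BestKeeperResult",
         representation(stats = "data.frame", index = "numeric",
                        ranks = "integer", undefined = "character",
                        sdMethod = "character"))

#' K-means clustering of expression profiles
#'
#' @slot cluster named integer, cluster id in 1..k per gene.
#' @slot centers k x samples centroid matrix.
#' @slot k number of clusters.
#' @slot seed RNG seed used.
#' @slot inertia total within-cluster sum of squares of the best restart.
#' @slot restarts number of k-means++ restarts evaluated.
#' @export
setClass("ClusterResult",
         representation(cluster = "integer", centers = "matrix",
                        k = "integer", seed = "integer", inertia = "numeric",
                        restarts = "integer"))

#' Relative expression by 2^-ddCt
#'
#' @slot table data.frame: target, sample, dCt, ddCt, foldChange.
#' @slot refs reference gene set used for the normalization factor.
#' @slot calibrator calibrator sample or group identifier.
#' @slot calibratorType "sample" or "group".
#' @export
setClass("RelativeExpression",
         representation(table = "data.frame", refs = "character",
                        calibrator = "character", calibratorType = "character"))

#' Generating parameters of a synthetic Ct dataset
#'
#' The additive model is
#' \deqn{Ct_{igr} = \mu_i + \delta_{ig} + s_j + e_{ij} + \epsilon_r}
#' with gene baselines \eqn{\mu_i}, inter-group shifts \eqn{\delta_{ig}}
#' (centered per gene), a per-sample loading shift \eqn{s_j} shared by all
#' genes, intra-group noise \eqn{e_{ij} \sim N(0,\sigma_i)} and technical
#' replicate noise \eqn{\epsilon_r \sim N(0,\sigma_{rep})}.
#'
#' @slot nGenes,nGroups,samplesPerGroup,replicates dimensions.
#' @slot mu per-gene baseline Ct (cycles).
#' @slot sigma per-gene intra-group SD (cycles).
#' @slot delta gene x group shift matrix (cycles), rows centered.
#' @slot sampleShiftSD SD of the shared per-sample shift (cycles).
#' @slot sigmaRep technical replicate SD (cycles).
#' @slot seed RNG seed.
#' @export
setClass("SimulationParams",
         representation(nGenes = "integer", nGroups = "integer",
                        samplesPerGroup = "integer", replicates = "integer",
                        mu = "numeric", sigma = "numeric", delta = "matrix",
                        sampleShiftSD = "numeric", sigmaRep = "numeric",
                        seed = "integer"),
         validity = function(object) {
             msg <- character()
             if (any(c(object@nGenes, object@nGroups, object@samplesPerGroup,
                       object@replicates) < 1L))
                 msg <- c(msg, "all dimensions must be >= 1")
             if (length(object@mu) != object@nGenes)
                 msg <- c(msg, "mu must have one value per gene")
             if (length(object@sigma) != object@nGenes)
                 msg <- c(msg, "sigma must have one value per gene")
             if (any(object@sigma < 0) || object@sigmaRep < 0 ||
                 object@sampleShiftSD < 0)
                 msg <- c(msg, "all SDs must be >= 0")
             if (!all(dim(object@delta) == c(object@nGenes, object@nGroups)))
                 msg <- c(msg, "delta must be nGenes x nGroups")
             if (length(msg)) msg else TRUE
         })

#' Ground truth paired with a synthetic Ct dataset
#'
#' @slot params the \linkS4class{SimulationParams} used.
#' @slot totalPerturbation per gene, \eqn{\sigma_i^2 + Var_g(\delta_{ig})}
#'   (population variance over groups).
#' @slot stabilityOrder genes sorted by increasing total perturbation (the
#'   ideal stability ordering; a permutation of the gene set).
#' @export
setClass("SimulationTruth",
         representation(params = "SimulationParams",
                        totalPerturbation = "numeric",
                        stabilityOrder = "character"),
         validity = function(object) {
             if (!setequal(object@stabilityOrder,
                           names(object@totalPerturbation)))
                 "stabilityOrder must be a permutation of the gene set"
             else TRUE
         })
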