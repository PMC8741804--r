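# Synthetic qRT-PCR data with known ground truth. The Ct generator follows
# the additive variance-component model the stability algorithms assume:
# a per-gene baseline, centered inter-group shifts, a per-sample loading
# shift shared across genes (common variation), intra-group biological noise
# and technical replicate noise, all on the cycle scale.

#' Build simulation parameters for a synthetic Ct matrix
#'
#' Defaults emulate a reference-gene screen in woody tissues: 12 candidate
#' genes, 4 tissue groups (X1-X4), 3 biological samples per group and 3
#' technical replicates, baseline Ct spread over 20-28 cycles, per-gene
#' intra-group SDs from 0.2 to 2 cycles and inter-group shift SDs from 0 to
#' 1.5 cycles. When \code{delta} is not given, shifts are drawn once (from
#' \code{seed}) as centered normals with per-gene SD \code{deltaSD}.
#'
#' @param nGenes,nGroups,samplesPerGroup,replicates dimensions.
#' @param mu per-gene baseline Ct; default evenly spaced on 20-28.
#' @param sigma per-gene intra-group SD; default evenly spaced on 0.2-2.
#' @param delta nGenes x nGroups shift matrix (centered per gene), or NULL.
#' @param deltaSD per-gene SD used to draw \code{delta} when it is NULL;
#'   default evenly spaced on 0-1.5.
#' @param sampleShiftSD SD of the shared per-sample shift (cycles).
#' @param sigmaRep technical replicate SD (cycles).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return A \linkS4class{SimulationParams}.
#' @export
simulationParams <- function(nGenes = 12L, nGroups = 4L, samplesPerGroup = 3L,
                             replicates = 3L, mu = NULL, sigma = NULL,
                             delta = NULL, deltaSD = NULL,
                             sampleShiftSD = 0.3, sigmaRep = 0.15,
                             seed = 1L) {
    nGenes <- as.integer(nGenes); nGroups <- as.integer(nGroups)
    if (is.null(mu)) mu <- seq(20, 28, length.out = nGenes)
    if (is.null(sigma)) sigma <- seq(0.2, 2, length.out = nGenes)
    if (is.null(delta)) {
        if (is.null(deltaSD)) deltaSD <- seq(0, 1.5, length.out = nGenes)
        delta <- withr::with_seed(as.integer(seed), {
            d <- matrix(stats::rnorm(nGenes * nGroups, 0, rep(deltaSD, nGroups)),
                        nGenes, nGroups)
            d - rowMeans(d)
        })
    }
    new("SimulationParams", nGenes = nGenes, nGroups = nGroups,
        samplesPerGroup = as.integer(samplesPerGroup),
        replicates = as.integer(replicates),
        mu = as.numeric(mu), sigma = as.numeric(sigma), delta = delta,
        sampleShiftSD = sampleShiftSD, sigmaRep = sigmaRep,
        seed = as.integer(seed))
}

#' Simulate a Ct matrix with known ground truth
#'
#' Generates \eqn{Ct_{igr} = \mu_i + \delta_{ig} + s_j + e_{ij} + \epsilon_r}
#' with \eqn{e_{ij} \sim N(0, \sigma_i)}, \eqn{\epsilon_r \sim N(0,
#' \sigma_{rep})} and a per-sample shift \eqn{s_j \sim N(0, sampleShiftSD)}
#' shared by all genes. Output is reproducible bit-for-bit for a fixed seed.
#'
#' @param p a \linkS4class{SimulationParams}.
#' @return A list with elements \code{ct} (a \linkS4class{CtExperiment} with
#'   a replicate dimension when \code{replicates > 1} and tissue group labels
#'   \code{X1..Xg}) and \code{truth} (a \linkS4class{SimulationTruth}).
#' @export
simulateCtMatrix <- function(p) {
    stopifnot(is(p, "SimulationParams"))
    validObject(p)
    nS <- p@nGroups * p@samplesPerGroup
    genes <- sprintf("gene%02d", seq_len(p@nGenes))
    samples <- sprintf("S%02d", seq_len(nS))
    grp <- rep(sprintf("X%d", seq_len(p@nGroups)), each = p@samplesPerGroup)
    a <- withr::with_seed(p@seed, {
        s <- stats::rnorm(nS, 0, p@sampleShiftSD)
        e <- matrix(stats::rnorm(p@nGenes * nS, 0, p@sigma), p@nGenes, nS)
        base <- p@mu + p@delta[, rep(seq_len(p@nGroups),
                                     each = p@samplesPerGroup)] +
            matrix(s, p@nGenes, nS, byrow = TRUE) + e
        eps <- array(stats::rnorm(p@nGenes * nS * p@replicates, 0, p@sigmaRep),
                     c(p@nGenes, nS, p@replicates))
        array(rep(base, p@replicates), c(p@nGenes, nS, p@replicates)) + eps
    })
    dimnames(a) <- list(genes, samples, paste0("r", seq_len(p@replicates)))
    obj <- if (p@replicates == 1L) {
        m <- a[, , 1L, drop = TRUE]
        dim(m) <- c(p@nGenes, nS); dimnames(m) <- dimnames(a)[1:2]
        CtExperiment(m, groups = setNames(grp, samples))
    } else {
        CtExperiment(a, groups = setNames(grp, samples))
    }
    tot <- p@sigma^2 + apply(p@delta, 1L, function(d) mean((d - mean(d))^2))
    names(tot) <- genes
    truth <- new("SimulationTruth", params = p, totalPerturbation = tot,
                 stabilityOrder = genes[order(tot)])
    list(ct = obj, truth = truth)
}

#' Simulate a serial-dilution standard curve
#'
#' Points follow \eqn{Ct = intercept + slope \cdot \log_{10} q} with
#' \eqn{slope = -1/\log_{10}(1 + E/100)}; the most concentrated point sits at
#' \eqn{\log_{10} q = 0} and each further point is one \code{fold}-dilution
#' step down (fivefold by default).
#'
#' @param gene gene identifier.
#' @param efficiencyPct generating amplification efficiency in percent (> 0).
#' @param intercept Ct at log10 quantity 0.
#' @param nPoints number of dilution points (>= 3).
#' @param fold dilution factor between consecutive points.
#' @param noiseSD SD of additive normal Ct noise.
#' @param seed RNG seed (required when \code{noiseSD > 0}).
#' @return A \linkS4class{DilutionSeries}.
#' @export
simulateDilutionSeries <- function(gene = "gene", efficiencyPct = 100,
                                   intercept = 30, nPoints = 6L, fold = 5,
                                   noiseSD = 0, seed = NULL) {
    if (efficiencyPct <= 0)
        stop("'efficiencyPct' must be > 0")
    lq <- -(seq_len(nPoints) - 1L) * log10(fold)
    slope <- -1 / log10(1 + efficiencyPct / 100)
    ct <- intercept + slope * lq
    if (noiseSD > 0) {
        if (is.null(seed))
            stop("'seed' is required when noiseSD > 0")
        ct <- ct + withr::with_seed(as.integer(seed),
                                    stats::rnorm(nPoints, 0, noiseSD))
    }
    new("DilutionSeries", gene = gene, log10Quantity = lq, ct = ct)
}

#' Simulate an FPKM-like abundance matrix with known fold changes
#'
#' Log-normal abundances: sample j in group g for gene i has value
#' \eqn{baseline_i \cdot FC_{ig} \cdot \exp(N(0, dispersion))}, so with zero
#' dispersion the group means realise the fold changes exactly and in
#' expectation the ratio of group means equals \eqn{FC_{ig}/FC_{ig'}} for any
#' dispersion.
#'
#' @param nGenes number of genes.
#' @param groups character vector of group labels, one per sample.
#' @param foldChanges nGenes x nGroups matrix of fold changes relative to the
#'   first group (first column should be 1); recycled from a vector of
#'   per-gene fold changes applied to the last group when a matrix is not
#'   given.
#' @param baseline per-gene baseline abundance (default 50).
#' @param dispersion SD of the log-normal noise on the natural-log scale.
#' @param seed RNG seed.
#' @return An \linkS4class{FPKMExperiment}; the generating parameters are kept
#'   in \code{metadata(x)$truth}.
#' @export
simulateExpressionMatrix <- function(nGenes, groups, foldChanges = NULL,
                                     baseline = 50, dispersion = 0.2,
                                     seed = 1L) {
    groups <- as.character(groups)
    glev <- unique(groups)
    nGroups <- length(glev)
    if (is.null(foldChanges))
        foldChanges <- matrix(1, nGenes, nGroups)
    if (!is.matrix(foldChanges)) {
        fc <- matrix(1, nGenes, nGroups)
        fc[, nGroups] <- foldChanges
        foldChanges <- fc
    }
    stopifnot(nrow(foldChanges) == nGenes, ncol(foldChanges) == nGroups)
    baseline <- rep_len(baseline, nGenes)
    genes <- sprintf("gene%02d", seq_len(nGenes))
    samples <- sprintf("S%02d", seq_along(groups))
    gi <- match(groups, glev)
    m <- withr::with_seed(as.integer(seed), {
        mean.mat <- baseline * foldChanges[, gi, drop = FALSE]
        noise <- matrix(stats::rnorm(nGenes * length(groups), 0, dispersion),
                        nGenes, length(groups))
        mean.mat * exp(noise)
    })
    dimnames(m) <- list(genes, samples)
    out <- FPKMExperiment(m, groups = setNames(groups, samples))
    S4Vectors::metadata(out)$truth <- list(
        baseline = setNames(baseline, genes),
        foldChanges = matrix(foldChanges, nGenes, nGroups,
                             dimnames = list(genes, glev)),
        dispersion = dispersion, seed = as.integer(seed))
    out
}

setMethod("show", "SimulationParams", function(object) {
    cat("SimulationParams:", object@nGenes, "genes,", object@nGroups,
        "groups x", object@samplesPerGroup, "samples,",
        object@replicates, "replicates, seed", object@seed, "\n")
})

setMethod("show", "SimulationTruth", function(object) {
    cat("SimulationTruth: ideal stability order\n  ",
        paste(object@stabilityOrder, collapse = " < "), "\n")
})

#' Ground-truth accessors
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @return \code{totalPerturbation}: named numeric
#'   \eqn{\sigma_i^2 + Var_g(\delta_{ig})}; \code{stabilityOrder}: genes from
#'   most to least stable.
#' @export
totalPerturbation <- function(truth) truth@totalPerturbation

#' @rdname totalPerturbation
#' @export
stabilityOrder <- function(truth) truth@stabilityOrder
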