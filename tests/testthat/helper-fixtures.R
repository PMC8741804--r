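# Shared fixtures built in code.

# small named Ct matrix with reproducible noise
randomCtMatrix <- function(nGenes, nSamples, seed, base = 25, sd = 1) {
    withr::with_seed(seed, {
        m <- matrix(base + rnorm(nGenes * nSamples, 0, sd), nGenes, nSamples)
        dimnames(m) <- list(sprintf("g%02d", seq_len(nGenes)),
                            sprintf("s%02d", seq_len(nSamples)))
        m
    })
}

# independent brute-force geNorm M: explicit pair loops, no shared code path
bruteForceGeNormM <- function(ct) {
    q <- 2^(apply(ct, 1, min) - ct)
    n <- nrow(ct)
    M <- numeric(n)
    for (j in seq_len(n)) {
        vjk <- c()
        for (k in seq_len(n)) {
            if (k == j) next
            lr <- log2(q[j, ] / q[k, ])
            mu <- sum(lr) / length(lr)
            vjk <- c(vjk, sqrt(sum((lr - mu)^2) / (length(lr) - 1)))
        }
        M[j] <- mean(vjk)
    }
    setNames(M, rownames(ct))
}

# independent BestKeeper oracle: per-sample geometric mean via prod()^(1/n),
# Pearson r via the textbook sum formula
bruteForceBestKeeper <- function(ct) {
    ns <- ncol(ct)
    idx <- apply(ct, 2, function(col) prod(col)^(1 / length(col)))
    perGene <- function(v) {
        gm <- prod(v)^(1 / ns)
        am <- sum(v) / ns
        s <- sqrt(sum((v - am)^2) / (ns - 1))
        sx <- v - am; sy <- idx - mean(idx)
        r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
        c(gm = gm, am = am, min = min(v), max = max(v), sd = s,
          cv = 100 * s / am, r = r)
    }
    t(apply(ct, 1, perGene))
}

# simulation design with well-separated total perturbations: 8 genes whose
# true perturbations form a geometric ladder, randomly split between the
# intra-group and inter-group components, inter-group shifts sign-balanced
# and centered so the design is identifiable under normalization
nfRecoveryParams <- function(seed, samplesPerGroup = 10L) {
    withr::with_seed(seed, {
        tot <- 0.01 * 2.2^(0:7)
        prop <- runif(8)
        sigma <- sqrt(tot * prop)
        half <- sqrt(tot * (1 - prop))
        sgn <- sample(rep(c(-1, 1), 4))
        delta <- cbind(-half * sgn, half * sgn)
        delta <- sweep(delta, 2, colMeans(delta))
        simulationParams(nGenes = 8L, nGroups = 2L,
                         samplesPerGroup = samplesPerGroup, replicates = 1L,
                         mu = rep(25, 8), sigma = sigma, delta = delta,
                         sampleShiftSD = 0.3, sigmaRep = 0, seed = seed)
    })
}
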