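test_that("the noise-free limit reproduces the deterministic model exactly", {
    p <- simulationParams(nGenes = 3L, nGroups = 2L, samplesPerGroup = 2L,
                          replicates = 3L, mu = c(20, 24, 28),
                          sigma = rep(0, 3),
                          delta = matrix(0, 3, 2), sampleShiftSD = 0,
                          sigmaRep = 0, seed = 5L)
    a <- replicateArray(simulateCtMatrix(p)$ct)
    for (r in 1:3)
        expect_equal(unname(a[, , r]),
                     matrix(c(20, 24, 28), 3, 4), tolerance = 1e-12)
})

test_that("per-gene noise translates into sample variance ordering", {
    p <- simulationParams(nGenes = 2L, nGroups = 1L, samplesPerGroup = 50L,
                          replicates = 1L, mu = c(25, 25), sigma = c(0, 2),
                          delta = matrix(0, 2, 1), sampleShiftSD = 0,
                          sigmaRep = 0, seed = 3L)
    m <- ctValues(simulateCtMatrix(p)$ct)
    expect_lt(sd(m[1, ]), sd(m[2, ]))
})

test_that("a fixed seed reproduces the dataset bit-for-bit", {
    p <- simulationParams(seed = 42L)
    s1 <- simulateCtMatrix(p)
    s2 <- simulateCtMatrix(p)
    expect_identical(replicateArray(s1$ct), replicateArray(s2$ct))
    expect_identical(totalPerturbation(s1$truth),
                     totalPerturbation(s2$truth))
    s3 <- simulateCtMatrix(simulationParams(seed = 43L))
    expect_false(identical(replicateArray(s1$ct), replicateArray(s3$ct)))
})

test_that("truth orders genes by total perturbation", {
    p <- simulationParams(seed = 7L)
    tr <- simulateCtMatrix(p)$truth
    tot <- totalPerturbation(tr)
    expect_setequal(stabilityOrder(tr), names(tot))
    expect_identical(stabilityOrder(tr), names(tot)[order(tot)])
})

test_that("dilution series follow the efficiency/slope closed form", {
    d <- simulateDilutionSeries(efficiencyPct = 100, nPoints = 5)
    slope <- diff(d@ct) / diff(d@log10Quantity)
    expect_equal(unname(slope), rep(-1 / log10(2), 4), tolerance = 1e-12)
    expect_equal(d@log10Quantity[2] - d@log10Quantity[1], -log10(5))
    expect_error(simulateDilutionSeries(efficiencyPct = 0), "> 0")
    expect_error(simulateDilutionSeries(efficiencyPct = -5), "> 0")
})

test_that("fitting a noise-free series inverts the generator exactly", {
    for (E in c(70, 88.1, 100, 110, 134.5)) {
        f <- fitStandardCurve(simulateDilutionSeries(efficiencyPct = E))
        expect_equal(f@efficiency, E, tolerance = 1e-9)
    }
})

test_that("noisy dilution series recover the efficiency on average", {
    est <- vapply(1:100, function(s) {
        d <- simulateDilutionSeries(efficiencyPct = 90, nPoints = 6,
                                    noiseSD = 0.05, seed = s)
        fitStandardCurve(d)@efficiency
    }, numeric(1))
    expect_lt(abs(mean(est) - 90), 2)
})

test_that("expression simulation honors fold changes and seeds", {
    groups <- rep(c("X1", "X2"), each = 3)
    fc <- matrix(c(1, 1, 1, 4, 0.5, 1), 3, 2)
    e0 <- simulateExpressionMatrix(3, groups, fc, dispersion = 0, seed = 1)
    m0 <- exprValues(e0)
    expect_equal(unname(rowMeans(m0[, 4:6]) / rowMeans(m0[, 1:3])),
                 c(4, 0.5, 1), tolerance = 1e-12)
    e1 <- simulateExpressionMatrix(3, groups, fc, dispersion = 0.3, seed = 9)
    e2 <- simulateExpressionMatrix(3, groups, fc, dispersion = 0.3, seed = 9)
    expect_identical(exprValues(e1), exprValues(e2))
    # mean recovered fold change over 100 seeds
    rec <- vapply(1:100, function(s) {
        m <- exprValues(simulateExpressionMatrix(3, groups, fc,
                                                 dispersion = 0.3, seed = s))
        (rowMeans(m[, 4:6]) / rowMeans(m[, 1:3]))[1]
    }, numeric(1))
    expect_lt(abs(mean(rec) - 4) / 4, 0.05)
})

test_that("empirical variance components match the generating parameters", {
    # intra-group noise, one group, no other variation
    pA <- simulationParams(nGenes = 4L, nGroups = 1L, samplesPerGroup = 600L,
                           replicates = 1L, mu = rep(25, 4),
                           sigma = c(0.3, 0.8, 1.2, 2),
                           delta = matrix(0, 4, 1), sampleShiftSD = 0,
                           sigmaRep = 0, seed = 101L)
    mA <- ctValues(simulateCtMatrix(pA)$ct)
    expect_equal(unname(apply(mA, 1, var)), c(0.3, 0.8, 1.2, 2)^2,
                 tolerance = 0.1)
    # inter-group shifts from group means
    delta <- matrix(c(-1, 0.4, 1, -0.4, 0, 0, 0, 0), 2, 4)
    pB <- simulationParams(nGenes = 2L, nGroups = 4L, samplesPerGroup = 250L,
                           replicates = 1L, mu = c(24, 26),
                           sigma = c(0.2, 0.2), delta = delta,
                           sampleShiftSD = 0, sigmaRep = 0, seed = 102L)
    sim <- simulateCtMatrix(pB)
    m <- ctValues(sim$ct); g <- sampleGroups(sim$ct)
    dEst <- t(vapply(levels(g), function(l)
        rowMeans(m[, g == l]), numeric(2))) # groups x genes
    varD <- apply(dEst, 2, function(v) mean((v - mean(v))^2))
    expect_equal(unname(varD),
                 unname(apply(delta, 1, function(d) mean((d - mean(d))^2))),
                 tolerance = 0.1)
    # technical replicate noise, pooled within cells
    pC <- simulationParams(nGenes = 6L, nGroups = 1L, samplesPerGroup = 100L,
                           replicates = 3L, mu = rep(25, 6),
                           sigma = rep(0.5, 6),
                           delta = matrix(0, 6, 1), sampleShiftSD = 0,
                           sigmaRep = 0.4, seed = 103L)
    a <- replicateArray(simulateCtMatrix(pC)$ct)
    pooled <- mean(apply(a, c(1, 2), var))
    expect_equal(pooled, 0.4^2, tolerance = 0.1)
})

test_that("invalid simulation dimensions are rejected", {
    expect_error(simulationParams(nGenes = 3L, mu = c(20, 25)),
                 "one value per gene")
    expect_error(simulationParams(nGenes = 2L, nGroups = 2L,
                                  mu = c(20, 25), sigma = c(-1, 1),
                                  delta = matrix(0, 2, 2)), ">= 0")
})
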