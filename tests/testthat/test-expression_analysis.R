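test_that("candidate screening applies all three filters", {
    tv <- rbind(flat = c(50, 55, 52, 49),
                low = c(3, 40, 42, 41),
                swing = c(10, 25, 12, 11),
                edge5 = c(5, 6, 7, 8))
    colnames(tv) <- paste0("X", 1:4)
    q <- matrix(0.9, 4, 6, dimnames = list(rownames(tv), NULL))
    expect_setequal(screenCandidateReferences(tv, q),
                    c("flat", "edge5"))          # FPKM >= 5 is inclusive
    q2 <- q; q2["flat", 3] <- 0.01               # significant somewhere
    expect_setequal(screenCandidateReferences(tv, q2), "edge5")
    expect_error(screenCandidateReferences(tv, q[1:2, ]), "missing")
})

test_that("the retained set equals a brute-force triple filter", {
    withr::with_seed(7, {
        tv <- matrix(runif(40 * 4, 1, 60), 40, 4,
                     dimnames = list(sprintf("g%02d", 1:40), paste0("X", 1:4)))
        q <- matrix(runif(40 * 6, 0, 0.3), 40, 6,
                    dimnames = list(rownames(tv), NULL))
    })
    got <- screenCandidateReferences(tv, q)
    want <- character(0)
    for (g in rownames(tv)) {
        keep <- TRUE
        for (v in tv[g, ]) if (v < 5) keep <- FALSE
        for (i in 1:4) for (j in 1:4)
            if (tv[g, i] / tv[g, j] >= 2) keep <- FALSE
        for (qq in q[g, ]) if (qq < 0.05) keep <- FALSE
        if (keep) want <- c(want, g)
    }
    expect_identical(got, want)
})

test_that("group labels turn samples into tissue means before screening", {
    m <- cbind(X1a = c(g1 = 10), X1b = c(g1 = 20), X2a = c(g1 = 14),
               X2b = c(g1 = 16))
    x <- FPKMExperiment(m, groups = c(X1a = "X1", X1b = "X1",
                                      X2a = "X2", X2b = "X2"))
    q <- matrix(1, 1, 1, dimnames = list("g1", NULL))
    # tissue means are 15 and 15: flat, despite sample-level spread of 2x
    expect_identical(screenCandidateReferences(x, q), "g1")
})

test_that("z-score standardization centers and scales each gene", {
    m <- rbind(a = c(1, 2, 3), b = c(10, 10, 10), c = c(5, 0, 7))
    colnames(m) <- paste0("s", 1:3)
    z <- zscoreStandardize(m)
    expect_equal(unname(z["a", ]), c(-1, 0, 1))          # sample SD = 1
    expect_equal(unname(z["b", ]), c(0, 0, 0))
    expect_identical(unname(attr(z, "constant")), c(FALSE, TRUE, FALSE))
    expect_equal(unname(rowMeans(z)), c(0, 0, 0), tolerance = 1e-12)
    expect_equal(sd(z["c", ]), 1, tolerance = 1e-12)
    zp <- zscoreStandardize(m, sdType = "population")
    expect_equal(unname(zp["a", ]), c(-1, 0, 1) * sqrt(3 / 2),
                 tolerance = 1e-12)
})

test_that("k-means recovers planted profile groups and is deterministic", {
    withr::with_seed(3, {
        up <- matrix(rep(c(-1, -1, 1, 1), each = 10), 10, 4) +
            rnorm(40, 0, 0.05)
        dn <- matrix(rep(c(1, 1, -1, -1), each = 10), 10, 4) +
            rnorm(40, 0, 0.05)
    })
    m <- rbind(up, dn)
    dimnames(m) <- list(sprintf("g%02d", 1:20), paste0("X", 1:4))
    cl <- kmeansCluster(m, k = 2, seed = 17)
    tab <- table(truth = rep(c("up", "dn"), each = 10),
                 cluster = clusterAssignments(cl))
    expect_identical(sort(unname(apply(tab, 1, max))), c(10L, 10L))
    expect_identical(clusterAssignments(kmeansCluster(m, k = 2, seed = 17)),
                     clusterAssignments(cl))
    expect_identical(dim(cl@centers), c(2L, 4L))
})

test_that("k = n gives singleton clusters with zero inertia", {
    m <- randomCtMatrix(5, 4, seed = 23)
    cl <- kmeansCluster(m, k = 5, seed = 1)
    expect_identical(sort(unname(clusterAssignments(cl))), 1:5)
    expect_equal(cl@inertia, 0)
    expect_error(kmeansCluster(m, k = 6, seed = 1), "exceed")
    expect_error(kmeansCluster(m, k = 2), "seed")
})

test_that("clustering z-scores is invariant to per-gene affine rescaling", {
    withr::with_seed(9, {
        m <- matrix(runif(12 * 4, 1, 50), 12, 4,
                    dimnames = list(sprintf("g%02d", 1:12), paste0("X", 1:4)))
    })
    scaled <- m * withr::with_seed(10, runif(12, 0.5, 8)) +
        withr::with_seed(11, runif(12, 0, 20))
    z1 <- zscoreStandardize(m)
    z2 <- zscoreStandardize(scaled)
    expect_equal(z1, z2, tolerance = 1e-10)
    c1 <- kmeansCluster(z1, k = 3, seed = 5)
    c2 <- kmeansCluster(z2, k = 3, seed = 5)
    expect_identical(clusterAssignments(c1), clusterAssignments(c2))
})

test_that("four groups produce exactly the six pairwise comparisons", {
    e <- simulateExpressionMatrix(5, rep(paste0("X", 1:4), each = 3),
                                  dispersion = 0.1, seed = 2)
    de <- differentialExpressionFilter(e)
    expect_identical(de$comparisons,
                     c("X1_vs_X2", "X1_vs_X3", "X1_vs_X4",
                       "X2_vs_X3", "X2_vs_X4", "X3_vs_X4"))
    expect_identical(nrow(de$table), 30L)
    expect_length(de$anova, 5)
})

test_that("identical group means pass nothing; planted changes pass", {
    groups <- rep(c("X1", "X2"), each = 3)
    null <- simulateExpressionMatrix(20, groups, dispersion = 0, seed = 4)
    # zero dispersion -> exactly equal means -> fold 1, p = 1
    deNull <- differentialExpressionFilter(null)
    expect_false(any(deNull$table$pass))
    fc <- matrix(c(rep(1, 3), 6525, 3, 1), 3, 2)
    big <- simulateExpressionMatrix(3, groups, fc, dispersion = 0.05,
                                    seed = 6)
    de <- differentialExpressionFilter(big)
    expect_true(de$table$pass[de$table$gene == "gene01"])
    expect_gt(de$table$foldChange[de$table$gene == "gene01"], 2000)
    expect_true(de$table$pass[de$table$gene == "gene02"])
    expect_false(de$table$pass[de$table$gene == "gene03"])
})

test_that("pass flags equal brute-force evaluation of both rules", {
    groups <- rep(paste0("X", 1:3), each = 4)
    e <- simulateExpressionMatrix(15, groups,
                                  matrix(withr::with_seed(5,
                                      sample(c(1, 1, 3, 0.2), 45,
                                             replace = TRUE)), 15, 3),
                                  dispersion = 0.3, seed = 5)
    de <- differentialExpressionFilter(e)
    m <- exprValues(e); g <- sampleGroups(e)
    for (k in seq_len(nrow(de$table))) {
        row <- de$table[k, ]
        gs <- strsplit(row$comparison, "_vs_")[[1]]
        a <- m[row$gene, g == gs[1]]; b <- m[row$gene, g == gs[2]]
        fc <- mean(a) / mean(b); fc <- max(fc, 1 / fc)
        p <- t.test(log2(a), log2(b))$p.value
        expect_equal(row$foldChange, fc, tolerance = 1e-12)
        expect_equal(row$p, p, tolerance = 1e-12)
        expect_identical(row$pass, fc > 2 && p < 0.05)
    }
})

test_that("raising the fold threshold never adds passing genes", {
    groups <- rep(c("X1", "X2"), each = 4)
    e <- simulateExpressionMatrix(30, groups,
                                  matrix(c(rep(1, 30),
                                           withr::with_seed(8,
                                               runif(30, 0.2, 5))), 30, 2),
                                  dispersion = 0.2, seed = 8)
    p2 <- differentialExpressionFilter(e, foldThreshold = 2)$table$pass
    p4 <- differentialExpressionFilter(e, foldThreshold = 4)$table$pass
    expect_true(all(which(p4) %in% which(p2)))
})

test_that("groups without replication error in strict mode only", {
    m <- matrix(c(10, 20, 12, 24), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
    expect_error(differentialExpressionFilter(m, groups = c("X1", "X2")),
                 "replicates")
    de <- differentialExpressionFilter(m, groups = c("X1", "X2"),
                                       strict = FALSE)
    expect_true(all(is.na(de$table$p)))
    expect_equal(de$table$foldChange, c(12 / 10, 24 / 20), tolerance = 1e-12)
})
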