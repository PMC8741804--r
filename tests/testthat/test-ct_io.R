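test_that("wide Ct tables round-trip through write and read", {
    m <- matrix(c(20.5, 24.25, 21.125, 25.75), 2, 2,
                dimnames = list(c("GAPDH", "H2B"), c("S1", "S2")))
    x <- CtExperiment(m, groups = c(S1 = "X1", S2 = "X2"))
    f <- withr::local_tempfile(fileext = ".csv")
    writeCtTable(x, f)
    y <- readCtTable(f)
    expect_identical(dim(ctValues(y)), c(2L, 2L))
    expect_identical(ctValues(y), m)
    expect_identical(rownames(y), c("GAPDH", "H2B"))  # order preserved

    e <- matrix(runif(12, 1, 100), 3, 4,
                dimnames = list(paste0("g", 1:3), paste0("t", 1:4)))
    fx <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionTable(FPKMExperiment(e), fx, sep = "\t")
    expect_equal(exprValues(readExpressionTable(fx)), e)
})

test_that("long-format tables with replicates round-trip", {
    a <- array(20 + seq_len(12) / 10, c(2, 2, 3),
               dimnames = list(c("gA", "gB"), c("S1", "S2"),
                               c("r1", "r2", "r3")))
    x <- CtExperiment(a)
    f <- withr::local_tempfile(fileext = ".csv")
    writeCtTable(x, f, format = "long")
    y <- readCtTable(f)
    expect_true(hasReplicates(y))
    expect_identical(dim(replicateArray(y))[3], 3L)
    expect_equal(replicateArray(y), a, ignore_attr = TRUE)

    # wide with replicate-suffixed columns
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeCtTable(x, f2, format = "wide")
    y2 <- readCtTable(f2)
    expect_true(hasReplicates(y2))
    expect_equal(replicateArray(y2), a, ignore_attr = TRUE)
})

test_that("malformed tables are rejected with the offending cell named", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("gene,S1,S2", "gA,20.1,oops", "gB,21.0,22.0"), f)
    expect_error(readCtTable(f), "oops.*row 1.*S2")

    writeLines(c("gene,S1,S2", "gA,20.1,NA", "gB,21.0,22.0"), f)
    expect_error(readCtTable(f), "missing Ct.*gA.*S2")

    writeLines(c("gene,S1,S2", "gA,20.1,21.0", "gA,21.0,22.0"), f)
    expect_error(readCtTable(f), "duplicate gene")

    writeLines(c("gene,S1,S2", "gA,20.1,-3", "gB,21.0,22.0"), f)
    expect_error(readCtTable(f), "finite and > 0")

    fe <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("gene,t1,t2", "gA,5,-1"), fe)
    expect_error(readExpressionTable(fe), "negative value.*gA.*t2")
})

test_that("the drop_sample policy removes whole samples with missing Ct", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("gene,S1,S2,S3", "gA,20,NA,22", "gB,21,23,24"), f)
    x <- readCtTable(f, missing = "drop_sample")
    expect_identical(colnames(x), c("S1", "S3"))
    expect_false(anyNA(ctValues(x)))
})

test_that("collapseReplicates averages cells and reports replicate SD", {
    a <- array(NA_real_, c(2, 1, 3),
               dimnames = list(c("gA", "gB"), "S1", c("r1", "r2", "r3")))
    a["gA", 1, ] <- c(20, 20, 20)
    a["gB", 1, ] <- c(20, 21, 22)
    x <- collapseReplicates(CtExperiment(a))
    expect_identical(unname(ctValues(x)["gA", 1]), 20)
    expect_identical(unname(ctValues(x)["gB", 1]), 21)
    expect_equal(unname(SummarizedExperiment::assay(x, "ct_sd")["gB", 1]),
                 sd(c(20, 21, 22)))
})

test_that("collapsed values equal cell-by-cell means and are replicate-order invariant", {
    a <- withr::with_seed(11, array(25 + rnorm(4 * 5 * 3), c(4, 5, 3)))
    dimnames(a) <- list(paste0("g", 1:4), paste0("s", 1:5), paste0("r", 1:3))
    x <- collapseReplicates(CtExperiment(a))
    ref <- matrix(NA_real_, 4, 5)
    for (i in 1:4) for (j in 1:5) ref[i, j] <- mean(a[i, j, ])
    expect_equal(unname(ctValues(x)), ref)
    perm <- a[, , c(3, 1, 2)]
    dimnames(perm)[[3]] <- dimnames(a)[[3]]
    expect_equal(ctValues(collapseReplicates(CtExperiment(perm))),
                 ctValues(x))
})

test_that("group designs attach to samples and validate", {
    m <- randomCtMatrix(3, 4, seed = 2)
    g <- setNames(c("X1", "X1", "X2", "X2"), colnames(m))
    x <- CtExperiment(m, groups = g)
    expect_identical(as.character(sampleGroups(x)), unname(g))
    fg <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample,group", paste(names(g), g, sep = ",")), fg)
    f <- withr::local_tempfile(fileext = ".csv")
    writeCtTable(x, f)
    y <- readCtTable(f, groups = fg)
    expect_identical(sampleGroups(y), sampleGroups(x))
    expect_error(CtExperiment(m, groups = c(s01 = "X1")), "missing")
})
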