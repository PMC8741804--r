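# Construction, accessors and delimited-text I/O for Ct and abundance
# matrices. Wide format: first column gene id, header row of sample ids;
# technical replicates either as duplicated sample columns or as columns with
# an "_r<k>" suffix. Long format: columns gene, sample, replicate, ct.

#' Construct a CtExperiment
#'
#' @param ct numeric matrix (genes x samples) or 3-d array
#'   (genes x samples x replicates) of Ct values; dimnames required. Ragged
#'   replicate counts are padded with \code{NA} in the third dimension.
#' @param groups optional group labels: a named vector/factor (names =
#'   samples) or an unnamed vector in column order.
#' @return A \linkS4class{CtExperiment}.
#' @examples
#' m <- matrix(c(20, 24, 21, 25), 2, 2,
#'             dimnames = list(c("GAPDH", "H2B"), c("S1", "S2")))
#' CtExperiment(m, groups = c(S1 = "X1", S2 = "X2"))
#' @export
CtExperiment <- function(ct, groups = NULL) {
    if (is.null(dimnames(ct)[[1]]) || is.null(dimnames(ct)[[2]]))
        stop("'ct' must carry gene (row) and sample (column) names")
    samples <- dimnames(ct)[[2]]
    cd <- S4Vectors::DataFrame(row.names = samples)
    if (!is.null(groups)) {
        if (!is.null(names(groups))) {
            if (!all(samples %in% names(groups)))
                stop("groups missing for sample(s): ",
                     paste(setdiff(samples, names(groups)), collapse = ", "))
            groups <- groups[samples]
        } else if (length(groups) != length(samples)) {
            stop("unnamed 'groups' must match the number of samples")
        }
        cd$group <- factor(as.character(groups))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ct = ct), colData = cd)
    new("CtExperiment", se)
}

#' Construct an FPKMExperiment
#'
#' @param expr non-negative numeric matrix (genes x samples) with dimnames.
#' @param groups optional group labels as in [CtExperiment()].
#' @return An \linkS4class{FPKMExperiment}.
#' @export
FPKMExperiment <- function(expr, groups = NULL) {
    if (is.null(rownames(expr)) || is.null(colnames(expr)))
        stop("'expr' must carry gene (row) and sample (column) names")
    cd <- S4Vectors::DataFrame(row.names = colnames(expr))
    if (!is.null(groups)) {
        if (!is.null(names(groups))) groups <- groups[colnames(expr)]
        cd$group <- factor(as.character(groups))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = expr), colData = cd)
    new("FPKMExperiment", se)
}

#' Access Ct values and technical replicates
#'
#' \code{ctValues} returns the genes x samples Ct matrix (collapsing
#' replicates by their mean on the fly when present);
#' \code{replicateArray} the raw 3-d replicate array (or \code{NULL});
#' \code{hasReplicates} whether an uncollapsed replicate dimension exists.
#'
#' @param x a \linkS4class{CtExperiment}.
#' @param ... unused.
#' @return \code{ctValues}: numeric matrix; \code{replicateArray}: 3-d array
#'   or \code{NULL}; \code{hasReplicates}: logical.
#' @name ctValues
#' @aliases replicateArray hasReplicates
NULL

#' @rdname ctValues
#' @export
setMethod("ctValues", "CtExperiment", function(x, ...) {
    a <- SummarizedExperiment::assay(x, "ct")
    if (length(dim(a)) == 3L)
        a <- apply(a, c(1L, 2L), mean, na.rm = TRUE)
    a
})

#' @rdname ctValues
#' @export
setMethod("replicateArray", "CtExperiment", function(x) {
    a <- SummarizedExperiment::assay(x, "ct")
    if (length(dim(a)) == 3L) a else NULL
})

#' @rdname ctValues
#' @export
setMethod("hasReplicates", "CtExperiment", function(x) {
    length(dim(SummarizedExperiment::assay(x, "ct"))) == 3L
})

#' Sample group labels
#'
#' @param x a \linkS4class{CtExperiment} or \linkS4class{FPKMExperiment}.
#' @return Named factor of group labels, or \code{NULL} when absent.
#' @export
setMethod("sampleGroups", "SummarizedExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!("group" %in% colnames(cd))) return(NULL)
    setNames(cd$group, rownames(cd))
})

#' Collapse technical replicates to their mean
#'
#' Removes the replicate dimension; each gene x sample cell becomes the
#' arithmetic mean of its replicates, and the per-cell replicate standard
#' deviation is kept as assay \code{"ct_sd"} for QC.
#'
#' @param x a \linkS4class{CtExperiment} with a replicate dimension.
#' @param method aggregation method; only \code{"mean"} is supported.
#' @return A \linkS4class{CtExperiment} with matrix assays \code{"ct"} and
#'   \code{"ct_sd"}.
#' @export
setMethod("collapseReplicates", "CtExperiment", function(x, method = "mean") {
    method <- match.arg(method, "mean")
    a <- replicateArray(x)
    if (is.null(a))
        stop("no replicate dimension to collapse")
    m <- apply(a, c(1L, 2L), mean, na.rm = TRUE)
    s <- apply(a, c(1L, 2L), function(v) {
        v <- v[!is.na(v)]
        if (length(v) > 1L) stats::sd(v) else 0
    })
    out <- CtExperiment(m, groups = sampleGroups(x))
    SummarizedExperiment::assays(out)$ct_sd <- s
    out
})

#' Access abundance values
#'
#' @param x an \linkS4class{FPKMExperiment}.
#' @return The genes x samples abundance matrix.
#' @export
setMethod("exprValues", "FPKMExperiment", function(x) {
    SummarizedExperiment::assay(x, "expr")
})

setMethod("show", "CtExperiment", function(object) {
    a <- SummarizedExperiment::assay(object, "ct")
    cat("CtExperiment:", nrow(object), "genes x", ncol(object), "samples")
    if (length(dim(a)) == 3L)
        cat(" x", dim(a)[3L], "replicates (uncollapsed)")
    cat("\n")
    g <- sampleGroups(object)
    if (!is.null(g))
        cat("groups:", paste(levels(g), collapse = ", "), "\n")
})

setMethod("show", "FPKMExperiment", function(object) {
    cat("FPKMExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
    g <- sampleGroups(object)
    if (!is.null(g))
        cat("groups:", paste(levels(g), collapse = ", "), "\n")
})

.detectSep <- function(path) {
    l <- readLines(path, n = 1L)
    if (lengths(regmatches(l, gregexpr("\t", l))) >=
        lengths(regmatches(l, gregexpr(",", l)))) "\t" else ","
}

.numifyCell <- function(df, what = "Ct") {
    # coerce all data columns to numeric, naming the first offending cell
    for (j in seq_along(df)) {
        v <- suppressWarnings(as.numeric(df[[j]]))
        bad <- which(is.na(v) & !is.na(df[[j]]) &
                     toupper(trimws(df[[j]])) != "NA")
        if (length(bad))
            stop(sprintf("non-numeric %s value '%s' at row %d, column '%s'",
                         what, df[bad[1L], j], bad[1L], colnames(df)[j]))
        df[[j]] <- v
    }
    df
}

#' Read a Ct table from delimited text
#'
#' Wide format: first column gene id, header of sample ids; replicate columns
#' are detected as duplicated sample names or an \code{_r<k>} suffix. Long
#' format: columns \code{gene, sample, replicate, ct}. The delimiter is
#' auto-detected (comma or tab).
#'
#' @param path file path.
#' @param format \code{"auto"}, \code{"wide"} or \code{"long"}.
#' @param missing \code{"error"} (default) rejects any missing Ct;
#'   \code{"drop_sample"} removes every sample containing a missing value so
#'   downstream algorithms see a complete matrix.
#' @param groups optional path to a two-column (sample, group) CSV, or a
#'   named vector of labels.
#' @return A validated \linkS4class{CtExperiment}; file ordering preserved.
#' @export
readCtTable <- function(path, format = c("auto", "wide", "long"),
                        missing = c("error", "drop_sample"), groups = NULL) {
    format <- match.arg(format)
    missing <- match.arg(missing)
    sep <- .detectSep(path)
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (format == "auto") {
        ln <- tolower(colnames(df))
        format <- if (ncol(df) == 4L &&
                      all(c("gene", "sample", "replicate", "ct") %in% ln))
            "long" else "wide"
    }
    if (is.character(groups) && length(groups) == 1L && file.exists(groups))
        groups <- readGroupTable(groups)
    if (format == "long") {
        colnames(df) <- tolower(colnames(df))
        ct <- suppressWarnings(as.numeric(df$ct))
        bad <- which(is.na(ct))
        if (length(bad) && any(toupper(trimws(df$ct[bad])) != "NA"))
            stop(sprintf("non-numeric Ct value '%s' at row %d, column 'ct'",
                         df$ct[bad[1L]], bad[1L]))
        genes <- unique(df$gene); samples <- unique(df$sample)
        if (length(bad)) {
            if (missing == "error")
                stop(sprintf("missing Ct at row %d (gene '%s', sample '%s')",
                             bad[1L], df$gene[bad[1L]], df$sample[bad[1L]]))
            drop <- unique(df$sample[bad])
            keep <- !(df$sample %in% drop)
            df <- df[keep, , drop = FALSE]; ct <- ct[keep]
            samples <- setdiff(samples, drop)
        }
        reps <- max(table(paste(df$gene, df$sample, sep = "\r")))
        a <- array(NA_real_, c(length(genes), length(samples), reps),
                   dimnames = list(genes, samples, paste0("r", seq_len(reps))))
        cnt <- new.env()
        for (k in seq_len(nrow(df))) {
            key <- paste(df$gene[k], df$sample[k], sep = "\r")
            i <- get0(key, cnt, ifnotfound = 0L) + 1L
            assign(key, i, cnt)
            a[df$gene[k], df$sample[k], i] <- ct[k]
        }
        if (dim(a)[3L] == 1L) {
            m <- a[, , 1L, drop = FALSE]; dim(m) <- dim(a)[1:2]
            dimnames(m) <- dimnames(a)[1:2]
            return(CtExperiment(m, groups = groups))
        }
        return(CtExperiment(a, groups = groups))
    }
    genes <- df[[1L]]
    if (anyDuplicated(genes))
        stop("duplicate gene identifier(s): ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    dat <- df[, -1L, drop = FALSE]
    dat <- .numifyCell(dat)
    m <- as.matrix(dat)
    rownames(m) <- genes
    if (anyNA(m)) {
        idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
        if (missing == "error")
            stop(sprintf("missing Ct at gene '%s', column '%s'",
                         genes[idx[1L]], colnames(m)[idx[2L]]))
        base <- sub("_r[0-9]+$", "", colnames(m))
        drop <- base %in% base[unique(which(is.na(m), arr.ind = TRUE)[, 2L])]
        m <- m[, !drop, drop = FALSE]
    }
    base <- sub("_r[0-9]+$", "", colnames(m))
    if (anyDuplicated(base)) {        # replicate columns
        samples <- unique(base)
        reps <- max(table(base))
        a <- array(NA_real_, c(nrow(m), length(samples), reps),
                   dimnames = list(genes, samples,
                                   paste0("r", seq_len(reps))))
        for (s in samples) {
            cols <- which(base == s)
            a[, s, seq_along(cols)] <- m[, cols]
        }
        return(CtExperiment(a, groups = groups))
    }
    CtExperiment(m, groups = groups)
}

#' Read a two-column sample/group design
#'
#' @param path CSV/TSV with columns (sample, group).
#' @return Named character vector, sample -> group label.
#' @export
readGroupTable <- function(path) {
    sep <- .detectSep(path)
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE)
    setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a Ct table
#'
#' @param x a \linkS4class{CtExperiment}.
#' @param path output file.
#' @param format \code{"wide"} (replicates become \code{_r<k>} columns) or
#'   \code{"long"}.
#' @param sep field delimiter.
#' @return \code{path}, invisibly.
#' @export
writeCtTable <- function(x, path, format = c("wide", "long"), sep = ",") {
    format <- match.arg(format)
    a <- replicateArray(x)
    if (format == "long") {
        if (is.null(a)) {
            m <- ctValues(x)
            df <- data.frame(gene = rep(rownames(m), times = ncol(m)),
                             sample = rep(colnames(m), each = nrow(m)),
                             replicate = 1L,
                             ct = as.vector(m))
        } else {
            df <- do.call(rbind, lapply(seq_len(dim(a)[3L]), function(r) {
                m <- a[, , r]
                data.frame(gene = rep(rownames(a), times = ncol(a)),
                           sample = rep(colnames(a), each = nrow(a)),
                           replicate = r, ct = as.vector(m))
            }))
            df <- df[!is.na(df$ct), , drop = FALSE]
        }
        utils::write.table(df, path, sep = sep, row.names = FALSE,
                           quote = FALSE)
        return(invisible(path))
    }
    if (is.null(a)) {
        m <- ctValues(x)
    } else {
        m <- do.call(cbind, lapply(seq_len(dim(a)[2L]), function(j) {
            sub <- a[, j, , drop = TRUE]
            colnames(sub) <- paste0(colnames(a)[j], "_r", seq_len(dim(a)[3L]))
            sub
        }))
        rownames(m) <- rownames(a)
    }
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read an abundance (FPKM / relative expression) table
#'
#' Wide delimited text, first column gene id; values must be non-negative.
#'
#' @inheritParams readCtTable
#' @return An \linkS4class{FPKMExperiment}.
#' @export
readExpressionTable <- function(path, groups = NULL) {
    sep <- .detectSep(path)
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    genes <- df[[1L]]
    if (anyDuplicated(genes))
        stop("duplicate gene identifier(s): ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    dat <- .numifyCell(df[, -1L, drop = FALSE], what = "expression")
    m <- as.matrix(dat)
    rownames(m) <- genes
    if (anyNA(m)) {
        idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
        stop(sprintf("missing value at gene '%s', column '%s'",
                     genes[idx[1L]], colnames(m)[idx[2L]]))
    }
    if (any(m < 0)) {
        idx <- which(m < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("negative value at gene '%s', column '%s'",
                     rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
    }
    if (is.character(groups) && length(groups) == 1L && file.exists(groups))
        groups <- readGroupTable(groups)
    FPKMExperiment(m, groups = groups)
}

#' Write an abundance table
#'
#' @param x an \linkS4class{FPKMExperiment}.
#' @param path output file.
#' @param sep field delimiter.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(x, path, sep = ",") {
    m <- exprValues(x)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    invisible(path)
}
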