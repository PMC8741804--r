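# End-to-end pipeline: simulate (or read) Ct data, fit efficiencies, run the
# three stability algorithms, merge them into the mean-rank consensus, then
# quantify targets and cluster/filter expression. Every stage is a pure
# function of its inputs and the config; outputs are CSV/JSON plus a small
# markdown report, with no timestamps, so a rerun under the same seed is
# byte-identical.

.readConfig <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        config <- if (grepl("\\.json$", config))
            jsonlite::read_json(config, simplifyVector = TRUE)
        else yaml::read_yaml(config)
    }
    stopifnot(is.list(config))
    config
}

.cfg <- function(config, key, default = NULL) {
    v <- config[[key]]
    if (is.null(v)) default else v
}

.writeCsv <- function(df, dir, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
    path
}

#' Run the full reference-gene stability pipeline
#'
#' Executes the enabled stages in dependency order: \code{simulate} (or read
#' Ct input), \code{efficiency}, \code{genorm}, \code{normfinder},
#' \code{bestkeeper}, \code{consensus}, \code{ddct}, \code{cluster},
#' \code{de}. Writes one CSV per stage plus \code{report.json} and
#' \code{report.md} into \code{outdir}. The advisory geNorm cutoff (M < 1.5)
#' is surfaced as a report annotation, never as a filter.
#'
#' @param config a list, or the path of a YAML/JSON file, with entries:
#'   \code{outdir} (required), \code{stages} (character vector; empty =
#'   no-op), \code{seed} (required when \code{simulate} or \code{cluster} is
#'   enabled), \code{ct} (path of a Ct table when not simulating),
#'   \code{groups} (path of a sample,group CSV), \code{simulate} (list of
#'   [simulationParams()] arguments), \code{dilution} (path of a
#'   gene,log10_quantity,ct CSV for the efficiency stage), \code{genorm}
#'   (list: \code{mCutoff}), \code{normfinder} (list: \code{grouped}),
#'   \code{bestkeeper} (list: \code{sdMethod}), \code{ddct} (list:
#'   \code{targets}, \code{refs}, \code{calibrator}), \code{expression}
#'   (path of an FPKM table for \code{cluster}/\code{de}), \code{cluster}
#'   (list: \code{k}, \code{nRestarts}), \code{de} (list:
#'   \code{foldThreshold}, \code{pThreshold}).
#' @return Invisibly, the report list (also serialized to
#'   \code{report.json}).
#' @export
runPipeline <- function(config) {
    config <- .readConfig(config)
    outdir <- .cfg(config, "outdir")
    if (is.null(outdir))
        stop("config must name an 'outdir'")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stages <- .cfg(config, "stages", character(0))
    report <- list(stages = stages, outputs = list(), annotations = list())
    runStage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    ct <- NULL
    truth <- NULL
    if ("simulate" %in% stages) {
        runStage("simulate", {
            seed <- .cfg(config, "seed")
            if (is.null(seed)) stop("a seed is required to simulate")
            args <- .cfg(config, "simulate", list())
            args$seed <- seed
            p <- do.call(simulationParams, args)
            sim <- simulateCtMatrix(p)
            ct <- if (hasReplicates(sim$ct)) collapseReplicates(sim$ct)
                   else sim$ct
            truth <- sim$truth
            writeCtTable(sim$ct, file.path(outdir, "ct.csv"))
            jsonlite::write_json(
                list(totalPerturbation = as.list(totalPerturbation(truth)),
                     stabilityOrder = stabilityOrder(truth)),
                file.path(outdir, "truth.json"), auto_unbox = TRUE,
                digits = NA)
            report$outputs$simulate <- c("ct.csv", "truth.json")
        })
    } else if (!is.null(.cfg(config, "ct"))) {
        ct <- readCtTable(.cfg(config, "ct"),
                          groups = .cfg(config, "groups"))
        if (hasReplicates(ct)) ct <- collapseReplicates(ct)
    }
    if ("efficiency" %in% stages) {
        runStage("efficiency", {
            path <- .cfg(config, "dilution")
            if (is.null(path)) stop("efficiency stage needs 'dilution'")
            df <- utils::read.table(path, sep = .detectSep(path),
                                    header = TRUE, stringsAsFactors = FALSE)
            fits <- lapply(split(df, df[[1L]]), function(d) {
                fitStandardCurve(new("DilutionSeries", gene = d[1L, 1L],
                                     log10Quantity = d[[2L]], ct = d[[3L]]))
            })
            tab <- do.call(rbind, lapply(fits, function(f)
                data.frame(gene = f@gene, slope = f@slope,
                           intercept = f@intercept, rSquared = f@rSquared,
                           efficiencyPct = f@efficiency, valid = f@valid)))
            report$outputs$efficiency <-
                basename(.writeCsv(tab, outdir, "efficiency.csv"))
        })
    }
    needCt <- intersect(stages, c("genorm", "normfinder", "bestkeeper",
                                  "ddct"))
    if (length(needCt) && is.null(ct))
        stop("stage '", needCt[1L], "' failed: no Ct input (enable ",
             "'simulate' or provide 'ct')", call. = FALSE)
    ranks <- list()
    if ("genorm" %in% stages) {
        runStage("genorm", {
            gn <- geNormRanking(ct)
            ranks$genorm <- gn
            report$outputs$genorm <-
                basename(.writeCsv(stabilityTable(gn), outdir, "genorm.csv"))
            jsonlite::write_json(
                list(pairwiseVariation = as.list(gn@pairwiseVariation),
                     recommendedN = gn@recommendedN, vCutoff = gn@vCutoff),
                file.path(outdir, "genorm_diagnostics.json"),
                auto_unbox = TRUE, digits = NA)
            mCut <- .cfg(.cfg(config, "genorm", list()), "mCutoff", 1.5)
            high <- names(gn@M)[gn@M >= mCut]
            if (length(high))
                report$annotations$genorm <- paste0(
                    "M >= ", mCut, " (advisory cutoff): ",
                    paste(high, collapse = ", "))
        })
    }
    if ("normfinder" %in% stages) {
        runStage("normfinder", {
            opts <- .cfg(config, "normfinder", list())
            nf <- normFinder(ct, grouped = .cfg(opts, "grouped", TRUE))
            ranks$normfinder <- nf
            report$outputs$normfinder <-
                basename(.writeCsv(stabilityTable(nf), outdir,
                                   "normfinder.csv"))
        })
    }
    if ("bestkeeper" %in% stages) {
        runStage("bestkeeper", {
            opts <- .cfg(config, "bestkeeper", list())
            bk <- bestKeeper(ct, sdMethod = .cfg(opts, "sdMethod", "sd"))
            ranks$bestkeeper <- bk
            report$outputs$bestkeeper <-
                basename(.writeCsv(cbind(bk@stats,
                                         rank = unname(bk@ranks)),
                                   outdir, "bestkeeper.csv"))
        })
    }
    if ("consensus" %in% stages) {
        runStage("consensus", {
            if (length(ranks) < 3L)
                stop("consensus needs the genorm, normfinder and ",
                     "bestkeeper stages")
            cons <- meanRankConsensus(ranks$genorm, ranks$normfinder,
                                      ranks$bestkeeper)
            report$outputs$consensus <-
                basename(.writeCsv(cons, outdir, "consensus.csv"))
            report$topGenes <- cons$gene[seq_len(min(4L, nrow(cons)))]
        })
    }
    if ("ddct" %in% stages) {
        runStage("ddct", {
            opts <- .cfg(config, "ddct", list())
            rx <- deltaDeltaCt(ct, targets = opts$targets,
                               refs = opts$refs,
                               calibrator = opts$calibrator)
            report$outputs$ddct <-
                basename(.writeCsv(rx@table, outdir, "ddct.csv"))
        })
    }
    expr <- NULL
    if (!is.null(.cfg(config, "expression")))
        expr <- readExpressionTable(.cfg(config, "expression"),
                                    groups = .cfg(config, "groups"))
    if ("cluster" %in% stages) {
        runStage("cluster", {
            if (is.null(expr)) stop("cluster stage needs 'expression'")
            seed <- .cfg(config, "seed")
            if (is.null(seed)) stop("a seed is required to cluster")
            opts <- .cfg(config, "cluster", list())
            z <- zscoreStandardize(expr)
            cl <- kmeansCluster(z, k = .cfg(opts, "k", 12L), seed = seed,
                                nRestarts = .cfg(opts, "nRestarts", 10L))
            report$outputs$cluster <-
                basename(.writeCsv(data.frame(gene = names(cl@cluster),
                                              cluster = unname(cl@cluster)),
                                   outdir, "clusters.csv"))
        })
    }
    if ("de" %in% stages) {
        runStage("de", {
            if (is.null(expr)) stop("de stage needs 'expression'")
            opts <- .cfg(config, "de", list())
            de <- differentialExpressionFilter(
                expr, foldThreshold = .cfg(opts, "foldThreshold", 2),
                pThreshold = .cfg(opts, "pThreshold", 0.05))
            report$outputs$de <-
                basename(.writeCsv(de$table, outdir, "de.csv"))
        })
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    md <- c("# refstab pipeline report", "",
            paste("Stages:", if (length(stages))
                paste(stages, collapse = ", ") else "(none)"), "")
    for (nm in names(report$outputs))
        md <- c(md, paste0("- ", nm, ": ",
                           paste(report$outputs[[nm]], collapse = ", ")))
    for (nm in names(report$annotations))
        md <- c(md, paste0("- note [", nm, "]: ",
                           report$annotations[[nm]]))
    if (!is.null(report$topGenes))
        md <- c(md, "",
                paste("Top consensus references:",
                      paste(report$topGenes, collapse = ", ")))
    writeLines(md, file.path(outdir, "report.md"))
    invisible(report)
}
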