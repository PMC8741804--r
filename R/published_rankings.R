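# Published per-algorithm stability orderings of the 12 candidate reference
# genes in radial-change woody tissues of Chinese fir stems (15- and
# 30-year-old trees), shipped as plain-text fixtures. Only each algorithm's
# top of the ordering was reported; the remaining genes carry filler
# positions (printed = FALSE) in a fixed arbitrary order, so consensus mean
# ranks are exact only for genes whose three positions are all printed.

#' Published stability orderings for Chinese fir radial-change tissues
#'
#' Loads the reported geNorm / NormFinder / BestKeeper orderings of 12
#' candidate reference genes in radial-change tissues of 15-year-old
#' (\code{"rc15"}) or 30-year-old (\code{"rc30"}) Chinese fir stems and
#' encodes them as \linkS4class{StabilityReport} objects (geNorm carries a
#' tied top pair). Positions beyond each algorithm's published list are
#' fillers; mean ranks that depend on them are internally consistent but not
#' reproductions of reported values.
#'
#' @param set \code{"rc15"} or \code{"rc30"}.
#' @return List with elements \code{genorm}, \code{normfinder},
#'   \code{bestkeeper} (StabilityReports) and \code{table} (the raw
#'   positions with their \code{printed} flag).
#' @examples
#' r <- publishedRankings("rc15")
#' meanRankConsensus(r$genorm, r$normfinder, r$bestkeeper)
#' @export
publishedRankings <- function(set = c("rc15", "rc30")) {
    set <- match.arg(set)
    path <- system.file("extdata", paste0(set, "_algorithm_rankings.csv"),
                        package = "refstab", mustWork = TRUE)
    df <- utils::read.table(path, sep = ",", header = TRUE,
                            stringsAsFactors = FALSE)
    mk <- function(alg) {
        sub <- df[df$algorithm == alg, ]
        pos <- setNames(as.numeric(sub$position), sub$gene)
        if (alg == "BestKeeper")           # higher r = more stable
            StabilityReport(alg, setNames(max(pos) + 1 - pos, names(pos)),
                            direction = "higher")
        else
            StabilityReport(alg, pos, direction = "lower")
    }
    list(genorm = mk("geNorm"), normfinder = mk("NormFinder"),
         bestkeeper = mk("BestKeeper"), table = df)
}
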