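#' @rdname ctValues
#' @export
setGeneric("ctValues", function(x, ...) standardGeneric("ctValues"))

#' @rdname ctValues
#' @export
setGeneric("replicateArray", function(x) standardGeneric("replicateArray"))

#' @rdname ctValues
#' @export
setGeneric("hasReplicates", function(x) standardGeneric("hasReplicates"))

#' @rdname sampleGroups
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname collapseReplicates
#' @export
setGeneric("collapseReplicates",
           function(x, method = "mean") standardGeneric("collapseReplicates"))

#' @rdname exprValues
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname assignDenseRanks
#' @export
setGeneric("assignDenseRanks",
           function(x, ...) standardGeneric("assignDenseRanks"))

#' @rdname stabilityTable
#' @export
setGeneric("stabilityTable", function(x) standardGeneric("stabilityTable"))

#' @rdname stabilityTable
#' @export
setGeneric("geneRanks", function(x) standardGeneric("geneRanks"))
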