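#' @rdname betaValues
#' @export
setGeneric("betaValues", function(x, ...) standardGeneric("betaValues"))

#' @rdname betaValues
#' @export
setGeneric("sampleRole", function(x, ...) standardGeneric("sampleRole"))

#' @rdname betaValues
#' @export
setGeneric("probeInfo", function(x, ...) standardGeneric("probeInfo"))

#' @rdname clusterMethylation
#' @export
setGeneric("clusterLabels", function(x, ...) standardGeneric("clusterLabels"))

#' @rdname rankOneDecompose
#' @export
setGeneric("sampleScores", function(x, ...) standardGeneric("sampleScores"))

#' @rdname rankOneDecompose
#' @export
setGeneric("probeLoadings", function(x, ...) standardGeneric("probeLoadings"))

#' @rdname callAberrations
#' @export
setGeneric("zScores", function(x, ...) standardGeneric("zScores"))

#' @rdname callAberrations
#' @export
setGeneric("aberrationCalls", function(x, ...)
    standardGeneric("aberrationCalls"))

#' @rdname fdrCurve
#' @export
setGeneric("fdrThreshold", function(x, ...) standardGeneric("fdrThreshold"))
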