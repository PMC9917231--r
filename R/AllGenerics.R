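#' @import methods
NULL

#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @export
setGeneric("drugNames", function(x) standardGeneric("drugNames"))

#' @export
setGeneric("targets", function(x, ...) standardGeneric("targets"))

#' @export
setGeneric("atcCodes", function(x) standardGeneric("atcCodes"))

#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @export
setGeneric("effectScores", function(x) standardGeneric("effectScores"))

#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))

#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))

#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @export
setGeneric("degreeSummary", function(x) standardGeneric("degreeSummary"))

#' @export
setGeneric("patternLabel", function(x) standardGeneric("patternLabel"))

#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @export
setGeneric("frequencyThreshold", function(x) standardGeneric("frequencyThreshold"))

#' @export
setGeneric("stopN", function(x) standardGeneric("stopN"))

#' @export
setGeneric("stableCandidates", function(x) standardGeneric("stableCandidates"))

#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))
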