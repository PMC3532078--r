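#' @rdname SimulationResult-class
#' @param x a SimulationResult
#' @export
setGeneric("alignment", function(x) standardGeneric("alignment"))

#' @rdname SimulationResult-class
#' @export
setGeneric("simulationRecord", function(x) standardGeneric("simulationRecord"))

#' @rdname SubstitutionMatrix-class
#' @param x an object with a branch length
#' @export
setGeneric("branchLength", function(x) standardGeneric("branchLength"))

#' @rdname SubstitutionMatrix-class
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname SimulationRecord-class
#' @param x a SimulationRecord
#' @export
setGeneric("edgeMatrices", function(x) standardGeneric("edgeMatrices"))

#' @rdname SimulationRecord-class
#' @export
setGeneric("rootDistribution", function(x) standardGeneric("rootDistribution"))
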