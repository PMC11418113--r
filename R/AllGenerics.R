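#' @rdname ConsensusResult-class
#' @param x a `ConsensusResult`
#' @param k factorization rank to extract (default: the chosen k)
#' @export
setGeneric("consensusMatrix",
           function(x, k) standardGeneric("consensusMatrix"))

#' @rdname ConsensusResult-class
#' @export
setGeneric("copheneticCoefficients",
           function(x) standardGeneric("copheneticCoefficients"))

#' @rdname ConsensusResult-class
#' @export
setGeneric("assignments", function(x, ...) standardGeneric("assignments"))

#' @rdname ConsensusResult-class
#' @export
setGeneric("silhouetteWidths",
           function(x) standardGeneric("silhouetteWidths"))

#' @rdname ConsensusResult-class
#' @export
setGeneric("retainedSamples", function(x) standardGeneric("retainedSamples"))

#' @rdname CompartmentProfiles-class
#' @param x a `CompartmentProfiles`
#' @export
setGeneric("cancerProfile", function(x) standardGeneric("cancerProfile"))

#' @rdname CompartmentProfiles-class
#' @export
setGeneric("stromaProfile", function(x) standardGeneric("stromaProfile"))

#' @rdname CompartmentProfiles-class
#' @export
setGeneric("clippedFlags", function(x) standardGeneric("clippedFlags"))

#' @rdname RiskModel-class
#' @param x a `RiskModel`
#' @export
setGeneric("riskGenes", function(x) standardGeneric("riskGenes"))

#' @rdname RiskModel-class
#' @export
setGeneric("riskCoefficients",
           function(x) standardGeneric("riskCoefficients"))

#' @rdname RiskModel-class
#' @export
setGeneric("riskCutpoint", function(x) standardGeneric("riskCutpoint"))

#' @rdname CellScores-class
#' @param x a `CellScores`
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname CellScores-class
#' @export
setGeneric("hybridCells", function(x) standardGeneric("hybridCells"))
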