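## Accessor generics. Slot access from user code is discouraged; these are the
## supported surface.

#' @rdname accessors
#' @param object a package object
#' @export
setGeneric("traces", function(object) standardGeneric("traces"))

#' @rdname accessors
#' @export
setGeneric("imagingRate", function(object) standardGeneric("imagingRate"))

#' @rdname accessors
#' @export
setGeneric("nNeurons", function(object) standardGeneric("nNeurons"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @rdname accessors
#' @export
setGeneric("nStimuli", function(object) standardGeneric("nStimuli"))

#' @rdname accessors
#' @export
setGeneric("kernelValues", function(object) standardGeneric("kernelValues"))

#' @rdname accessors
#' @export
setGeneric("factorActivity", function(object) standardGeneric("factorActivity"))

#' @rdname accessors
#' @export
setGeneric("factorCouplings", function(object) standardGeneric("factorCouplings"))

#' @rdname accessors
#' @export
setGeneric("stimulusFilters", function(object) standardGeneric("stimulusFilters"))

#' @rdname accessors
#' @export
setGeneric("noiseVariances", function(object) standardGeneric("noiseVariances"))

#' @rdname accessors
#' @export
setGeneric("fittedModel", function(object) standardGeneric("fittedModel"))

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))

#' @rdname accessors
#' @export
setGeneric("evokedTraces", function(object) standardGeneric("evokedTraces"))

#' @rdname accessors
#' @export
setGeneric("spontTraces", function(object) standardGeneric("spontTraces"))

#' @rdname accessors
#' @export
setGeneric("residualTraces", function(object) standardGeneric("residualTraces"))

#' @rdname accessors
#' @export
setGeneric("driveRatios", function(object) standardGeneric("driveRatios"))

#' @rdname accessors
#' @export
setGeneric("contributionIndices",
           function(object) standardGeneric("contributionIndices"))

#' Accessors for package classes
#'
#' Small accessor family: matrices, sizes and fitted quantities of
#' \linkS4class{FluorescenceSet}, \linkS4class{StimulusDesign},
#' \linkS4class{CalciumKernel}, \linkS4class{CilvaModel},
#' \linkS4class{CilvaFit} and \linkS4class{CilvaDecomposition}.
#'
#' @name accessors
#' @return the requested component
NULL

#' @rdname accessors
setMethod("traces", "FluorescenceSet", function(object) object@traces)
#' @rdname accessors
setMethod("imagingRate", "FluorescenceSet", function(object) object@fs)
#' @rdname accessors
setMethod("nNeurons", "FluorescenceSet", function(object) nrow(object@traces))
#' @rdname accessors
setMethod("nFrames", "FluorescenceSet", function(object) ncol(object@traces))
#' @rdname accessors
setMethod("nFrames", "StimulusDesign", function(object) ncol(object@design))
#' @rdname accessors
setMethod("designMatrix", "StimulusDesign", function(object) object@design)
#' @rdname accessors
setMethod("nStimuli", "StimulusDesign", function(object) nrow(object@design))
#' @rdname accessors
setMethod("kernelValues", "CalciumKernel", function(object) object@values)
#' @rdname accessors
setMethod("kernelValues", "CilvaModel", function(object) object@kernel@values)
#' @rdname accessors
setMethod("factorActivity", "CilvaModel", function(object) object@X)
#' @rdname accessors
setMethod("factorCouplings", "CilvaModel", function(object) object@B)
#' @rdname accessors
setMethod("stimulusFilters", "CilvaModel", function(object) object@W)
#' @rdname accessors
setMethod("noiseVariances", "CilvaModel", function(object) object@sigma2)
#' @rdname accessors
setMethod("fittedModel", "CilvaFit", function(object) object@model)
#' @rdname accessors
setMethod("objectiveTrace", "CilvaFit", function(object) object@objective)
#' @rdname accessors
setMethod("factorActivity", "CilvaFit", function(object) object@model@X)
#' @rdname accessors
setMethod("evokedTraces", "CilvaDecomposition", function(object) object@evoked)
#' @rdname accessors
setMethod("spontTraces", "CilvaDecomposition", function(object) object@spont)
#' @rdname accessors
setMethod("residualTraces", "CilvaDecomposition",
          function(object) object@residual)
#' @rdname accessors
setMethod("driveRatios", "CilvaDecomposition",
          function(object) object@driveRatio)
#' @rdname accessors
setMethod("contributionIndices", "CilvaDecomposition",
          function(object) object@contributionIndex)
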