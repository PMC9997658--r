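#' Accessors for TrackStates classes
#'
#' Small accessor generics: `trackId()`, `positions()`, `nFrames()`,
#' `nAxes()`, `frameInterval()`, `nStates()`, `diffusionLengths()`,
#' `localizationError()`, `initialFractions()`, `rateMatrix()`,
#' `stateProbabilities()`, `stateLabels()`, `fittedParams()`,
#' `groundTruth()`, `getTracks()`.
#'
#' @param object an object of the matching class.
#' @return The stored component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trackId", function(object) standardGeneric("trackId"))
#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nAxes", function(object) standardGeneric("nAxes"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setGeneric("diffusionLengths", function(object) standardGeneric("diffusionLengths"))
#' @rdname accessors
#' @export
setGeneric("localizationError", function(object) standardGeneric("localizationError"))
#' @rdname accessors
#' @export
setGeneric("initialFractions", function(object) standardGeneric("initialFractions"))
#' @rdname accessors
#' @export
setGeneric("rateMatrix", function(object) standardGeneric("rateMatrix"))
#' @rdname accessors
#' @export
setGeneric("stateProbabilities", function(object) standardGeneric("stateProbabilities"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("fittedParams", function(object) standardGeneric("fittedParams"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("getTracks", function(object) standardGeneric("getTracks"))

#' @rdname accessors
#' @export
setMethod("trackId", "Track", function(object) object@trackId)
#' @rdname accessors
#' @export
setMethod("positions", "Track", function(object) object@positions)
#' @rdname accessors
#' @export
setMethod("nFrames", "Track", function(object) nrow(object@positions))
#' @rdname accessors
#' @export
setMethod("nAxes", "Track", function(object) ncol(object@positions))
#' @rdname accessors
#' @export
setMethod("frameInterval", "Track", function(object) object@dt)
#' @rdname accessors
#' @export
setMethod("frameInterval", "TrackSet", function(object) object[[1L]]@dt)

#' @rdname accessors
#' @export
setMethod("nStates", "ModelParams", function(object) object@nStates)
#' @rdname accessors
#' @export
setMethod("diffusionLengths", "ModelParams", function(object) object@d)
#' @rdname accessors
#' @export
setMethod("localizationError", "ModelParams", function(object) object@sigma)
#' @rdname accessors
#' @export
setMethod("initialFractions", "ModelParams", function(object) object@F)
#' @rdname accessors
#' @export
setMethod("rateMatrix", "ModelParams", function(object) object@k)

#' @rdname accessors
#' @export
setMethod("fittedParams", "FitResult", function(object) object@params)
#' @rdname accessors
#' @export
setMethod("nStates", "FitResult", function(object) object@params@nStates)

#' @rdname accessors
#' @export
setMethod("trackId", "AnnotationResult", function(object) object@trackId)
#' @rdname accessors
#' @export
setMethod("stateProbabilities", "AnnotationResult", function(object) object@probs)
#' @rdname accessors
#' @export
setMethod("stateLabels", "AnnotationResult", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("trackId", "RefinedTrack", function(object) object@trackId)

#' @rdname accessors
#' @export
setMethod("getTracks", "SimulatedTracks", function(object) object@tracks)
#' @rdname accessors
#' @export
setMethod("groundTruth", "SimulatedTracks", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("logLik", "FitResult", function(object) object@logLik)
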