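#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `kappa()` returns
#' the coupling coefficient of a model or fit, `nChannels()` the channel
#' count, `occupancy()` the integer open-channel count per frame,
#' `traceValues()` the raw samples of a trace, `samplingInterval()` the frame
#' interval in seconds, and `quantalUnit()` the fitted elementary amplitude.
#'
#' @param object an object of one of the package's S4 classes.
#' @return the slot value; see the class documentation for units.
#' @name accessors
NULL

#' @rdname accessors
#' @param z an object (argument name follows the base `kappa` signature).
#' @param ... passed to the base method for non-package objects.
#' @export
setGeneric("kappa", function(z, ...) standardGeneric("kappa"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' @rdname accessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))

#' @rdname accessors
#' @export
setGeneric("samplingInterval",
           function(object) standardGeneric("samplingInterval"))

#' @rdname accessors
#' @export
setGeneric("quantalUnit", function(object) standardGeneric("quantalUnit"))

#' @rdname accessors
#' @export
setGeneric("isCoupled", function(object) standardGeneric("isCoupled"))

#' @rdname accessors
#' @export
setGeneric("nSteps", function(object) standardGeneric("nSteps"))

#' @rdname accessors
#' @export
setGeneric("clusterAreas", function(object) standardGeneric("clusterAreas"))
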