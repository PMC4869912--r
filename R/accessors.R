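## Accessors and show() methods.  Slot access stays inside the package;
## users go through these.

#' @rdname accessors
#' @aliases kappa,ANY-method
setMethod("kappa", "ANY", function(z, ...) base::kappa(z, ...))

#' @rdname accessors
setMethod("kappa", "CoupledGatingModel", function(z, ...) z@kappa)

#' @rdname accessors
setMethod("kappa", "CouplingFit", function(z, ...) z@kappaHat)

#' @rdname accessors
setMethod("nChannels", "CoupledGatingModel", function(object) object@nChannels)

#' @rdname accessors
setMethod("nChannels", "OccupancyTrace", function(object) object@nChannels)

#' @rdname accessors
setMethod("nChannels", "CouplingFit", function(object) object@nChannels)

#' @rdname accessors
setMethod("occupancy", "OccupancyTrace", function(object) object@k)

#' @rdname accessors
setMethod("traceValues", "SignalTrace", function(object) object@values)

#' @rdname accessors
setMethod("samplingInterval", "SignalTrace", function(object) object@dt)

#' @rdname accessors
setMethod("samplingInterval", "OccupancyTrace", function(object) object@dt)

#' @rdname accessors
setMethod("samplingInterval", "ImageStack", function(object) object@dt)

#' @rdname accessors
setMethod("quantalUnit", "QuantalFit", function(object) object@q)

#' @rdname accessors
setMethod("isCoupled", "CouplingFit", function(object) object@coupled)

#' @rdname accessors
setMethod("nSteps", "StepFit", function(object) object@nSteps)

#' @rdname accessors
setMethod("clusterAreas", "ClusterStats", function(object) object@areas)

#' Gating probabilities of a model or fit
#'
#' @param object a [CoupledGatingModel-class] or [CouplingFit-class].
#' @return named numeric vector c(pOpen = , pClose = ).
#' @export
gatingProbabilities <- function(object) {
  if (is(object, "CoupledGatingModel"))
    c(pOpen = object@pOpen, pClose = object@pClose)
  else if (is(object, "CouplingFit"))
    c(pOpen = object@pOpenHat, pClose = object@pCloseHat)
  else stop("no gating probabilities for class ", class(object))
}

#' Localization coordinates
#'
#' @param object a [LocalizationSet-class].
#' @return data.frame with columns x, y, photons, frame.
#' @export
localizations <- function(object) {
  stopifnot(is(object, "LocalizationSet"))
  object@coords
}

#' Sparklet events of a site
#'
#' @param object a [SparkletSite-class].
#' @return data.frame of events.
#' @export
sparkletEvents <- function(object) {
  stopifnot(is(object, "SparkletSite"))
  object@events
}

#' Pixel data of an image stack
#'
#' @param object an [ImageStack-class].
#' @return rows x cols x frames numeric array.
#' @export
stackData <- function(object) {
  stopifnot(is(object, "ImageStack"))
  object@data
}

setMethod("show", "CoupledGatingModel", function(object) {
  cat(sprintf(
    "CoupledGatingModel: N = %d, pOpen = %.4g, pClose = %.4g, kappa = %.3g\n",
    object@nChannels, object@pOpen, object@pClose, object@kappa))
})

setMethod("show", "OccupancyTrace", function(object) {
  cat(sprintf(
    "OccupancyTrace: %d frames, N = %d, dt = %.4g s, mean occupancy %.3g\n",
    length(object@k), object@nChannels, object@dt, mean(object@k)))
})

setMethod("show", "SignalTrace", function(object) {
  cat(sprintf("%s: %d frames, dt = %.4g s, range [%.4g, %.4g] %s\n",
              class(object), length(object@values), object@dt,
              min(object@values), max(object@values), object@units))
})

setMethod("show", "SweepSet", function(object) {
  cat(sprintf("SweepSet: %d sweeps x %d frames, dt = %.3g s, V = %g mV\n",
              ncol(object@sweeps), nrow(object@sweeps), object@dt,
              object@voltage))
})

setMethod("show", "QuantalFit", function(object) {
  cat(sprintf(
    "QuantalFit: q = %.4g, b = %.4g, %d components, residual = %.4g\n",
    object@q, object@b, object@nComponents, object@residual))
})

setMethod("show", "CouplingFit", function(object) {
  cat(sprintf(
    "CouplingFit: kappa = %.3f (%s, threshold %.2f), pOpen = %.4g, pClose = %.4g, logLik = %.2f\n",
    object@kappaHat, if (object@coupled) "coupled" else "uncoupled",
    object@threshold, object@pOpenHat, object@pCloseHat, object@logLik))
  if (length(object@flags)) cat("  flags:", object@flags, "\n")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack: %d x %d px, %d frames, %.3g nm/px, dt = %.4g s\n",
              d[1], d[2], d[3], object@pixelSize, object@dt))
})

setMethod("show", "StepFit", function(object) {
  cat(sprintf("StepFit: %d steps at frames [%s]\n", object@nSteps,
              paste(object@stepFrames, collapse = ", ")))
})

setMethod("show", "LocalizationSet", function(object) {
  cat(sprintf("LocalizationSet: %d localizations, DLR = %s nm\n",
              nrow(object@coords),
              if (is.na(object@dlr)) "NA" else format(object@dlr)))
})

setMethod("show", "ClusterStats", function(object) {
  cat(sprintf(
    "ClusterStats: %d clusters, mean area %.4g +/- %.3g nm^2, density %.4g / um^2\n",
    object@nClusters, object@meanArea, object@semArea, object@density))
})

setMethod("show", "SparkletSite", function(object) {
  cat(sprintf(
    "SparkletSite '%s': %d events, nPs = %.4g, Ps = %.3g, n levels = %d\n",
    object@siteId, nrow(object@events), object@nps, object@activeFraction,
    object@nLevels))
})

setMethod("show", "BoltzmannFit", function(object) {
  cat(sprintf("BoltzmannFit: V1/2 = %.3g mV, k = %.3g mV\n",
              object@vHalf, object@slopeK))
})
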