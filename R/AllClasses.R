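#' @import methods
#' @importFrom stats dnorm optim rnorm runif rpois rlnorm rbinom sd median
#'   quantile nls coef fitted resid t.test pt setNames var complete.cases
#' @importFrom utils head tail read.table write.table
#' @useDynLib coopgate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.PROB_MIN <- 1e-4
.PROB_MAX <- 0.9999

## ---------------------------------------------------------------------------
## Gating model
## ---------------------------------------------------------------------------

#' Binary coupled Markov-chain gating model
#'
#' Describes the per-frame gating of a cluster of \code{nChannels} identical
#' two-state (closed/open) channels.  The cluster-level transition kernel over
#' the occupancy (number of open channels) is the mixture
#' \deqn{T = (1 - \kappa) T_{ind} + \kappa T_{coh}}
#' where \eqn{T_{ind}} is the kernel of independently gating channels
#' (binomial closures and openings) and \eqn{T_{coh}} treats the cluster as a
#' single super-channel that opens and closes all-or-none.  \eqn{\kappa = 0}
#' is purely independent gating, \eqn{\kappa = 1} fully coupled gating.
#'
#' @slot nChannels integer, number of channels at the site (N >= 1).
#' @slot pOpen per-frame closed-to-open probability, strictly in (0, 1).
#' @slot pClose per-frame open-to-closed probability, strictly in (0, 1).
#' @slot kappa coupling coefficient in [0, 1].
#' @seealso [coupledGatingModel()], [transitionMatrix()], [estimateKappa()]
#' @export
setClass("CoupledGatingModel",
  representation(nChannels = "integer", pOpen = "numeric",
                 pClose = "numeric", kappa = "numeric"),
  prototype = prototype(nChannels = 1L, pOpen = 0.05, pClose = 0.5, kappa = 0))

setValidity("CoupledGatingModel", function(object) {
  msg <- character()
  if (length(object@nChannels) != 1L || is.na(object@nChannels) ||
      object@nChannels < 1L)
    msg <- c(msg, "nChannels must be a single integer >= 1")
  for (f in c("pOpen", "pClose")) {
    p <- slot(object, f)
    if (length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
      msg <- c(msg, sprintf("%s must be strictly inside (0, 1)", f))
  }
  if (length(object@kappa) != 1L || is.na(object@kappa) ||
      object@kappa < 0 || object@kappa > 1)
    msg <- c(msg, "kappa must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a coupled gating model
#'
#' @param nChannels number of channels at the site.
#' @param pOpen,pClose per-frame opening / closing probabilities in (0, 1).
#' @param kappa coupling coefficient; values outside [0, 1] are clipped.
#' @return A [CoupledGatingModel-class] object.
#' @examples
#' coupledGatingModel(nChannels = 2, pOpen = 0.03, pClose = 0.3, kappa = 0.21)
#' @export
coupledGatingModel <- function(nChannels, pOpen, pClose, kappa = 0) {
  new("CoupledGatingModel", nChannels = as.integer(nChannels),
      pOpen = as.numeric(pOpen), pClose = as.numeric(pClose),
      kappa = min(max(as.numeric(kappa), 0), 1))
}

## ---------------------------------------------------------------------------
## Traces
## ---------------------------------------------------------------------------

#' Uniformly sampled signal traces
#'
#' `SignalTrace` is the virtual parent of the three concrete trace classes:
#' [CalciumTrace-class] (sparklet records in nM), [CurrentTrace-class]
#' (currents in pA) and [BleachTrace-class] (photobleaching ROI intensity in
#' arbitrary units).
#'
#' @slot values numeric signal samples (finite).
#' @slot dt sampling interval in seconds (> 0).
#' @slot units character unit label.
#' @slot siteId character site/ROI label (may be empty).
#' @aliases CalciumTrace-class CurrentTrace-class BleachTrace-class
#' @export
setClass("SignalTrace",
  representation("VIRTUAL", values = "numeric", dt = "numeric",
                 units = "character", siteId = "character"))

setValidity("SignalTrace", function(object) {
  msg <- character()
  if (length(object@dt) != 1L || is.na(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "trace values must be finite")
  if (length(msg)) msg else TRUE
})

#' @export
setClass("CalciumTrace", contains = "SignalTrace",
         prototype = prototype(units = "nM", siteId = ""))
#' @export
setClass("CurrentTrace", contains = "SignalTrace",
         prototype = prototype(units = "pA", siteId = ""))
#' @export
setClass("BleachTrace", contains = "SignalTrace",
         prototype = prototype(units = "AU", siteId = ""))

#' Trace constructors
#'
#' @param values numeric samples.
#' @param dt sampling interval (s).
#' @param siteId optional site label.
#' @return the corresponding [SignalTrace-class] subclass.
#' @export
calciumTrace <- function(values, dt, siteId = "") {
  new("CalciumTrace", values = as.numeric(values), dt = as.numeric(dt),
      units = "nM", siteId = siteId)
}

#' @rdname calciumTrace
#' @export
currentTrace <- function(values, dt, siteId = "") {
  new("CurrentTrace", values = as.numeric(values), dt = as.numeric(dt),
      units = "pA", siteId = siteId)
}

#' @rdname calciumTrace
#' @export
bleachTrace <- function(values, dt, siteId = "") {
  new("BleachTrace", values = as.numeric(values), dt = as.numeric(dt),
      units = "AU", siteId = siteId)
}

#' Occupancy trace: number of open channels per frame
#'
#' The hidden state of the coupled gating chain: an integer count in
#' [0, nChannels] at every frame.
#'
#' @slot k integer occupancy per frame.
#' @slot nChannels total channels at the site.
#' @slot dt sampling interval (s).
#' @export
setClass("OccupancyTrace",
  representation(k = "integer", nChannels = "integer", dt = "numeric"))

setValidity("OccupancyTrace", function(object) {
  msg <- character()
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (length(object@k) &&
      (min(object@k) < 0L || max(object@k) > object@nChannels))
    msg <- c(msg, "occupancy values must lie in [0, nChannels]")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (length(msg)) msg else TRUE
})

#' @param k integer occupancy per frame.
#' @param nChannels total channels.
#' @param dt sampling interval (s).
#' @rdname OccupancyTrace-class
#' @export
occupancyTrace <- function(k, nChannels, dt) {
  new("OccupancyTrace", k = as.integer(k), nChannels = as.integer(nChannels),
      dt = as.numeric(dt))
}

## ---------------------------------------------------------------------------
## Single-channel containers
## ---------------------------------------------------------------------------

#' Set of single-channel current sweeps
#'
#' @slot sweeps numeric matrix, frames x sweeps (pA).
#' @slot dt sampling interval (s).
#' @slot voltage test potential (mV).
#' @export
setClass("SweepSet",
  representation(sweeps = "matrix", dt = "numeric", voltage = "numeric"))

setValidity("SweepSet", function(object) {
  msg <- character()
  if (!is.numeric(object@sweeps) || nrow(object@sweeps) < 1L)
    msg <- c(msg, "sweeps must be a non-empty numeric matrix")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (length(msg)) msg else TRUE
})

#' @param sweeps frames x sweeps numeric matrix.
#' @param dt sampling interval (s).
#' @param voltage test potential (mV).
#' @rdname SweepSet-class
#' @export
sweepSet <- function(sweeps, dt, voltage = NA_real_) {
  new("SweepSet", sweeps = as.matrix(sweeps), dt = as.numeric(dt),
      voltage = as.numeric(voltage))
}

#' All-points amplitude histogram
#'
#' Pools every sample of every sweep into fixed-width bins aligned so that
#' one bin center sits exactly at 0 pA.
#'
#' @slot binCenters bin centers (signal units).
#' @slot counts nonnegative integer counts; sums to the number of samples.
#' @slot binWidth bin width (signal units).
#' @export
setClass("AllPointsHistogram",
  representation(binCenters = "numeric", counts = "integer",
                 binWidth = "numeric"))

setValidity("AllPointsHistogram", function(object) {
  msg <- character()
  if (length(object@binCenters) != length(object@counts))
    msg <- c(msg, "binCenters and counts must have equal length")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be nonnegative")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
  if (length(msg)) msg else TRUE
})

#' Quantal multi-Gaussian fit
#'
#' Parameters of the quantal amplitude model fitted to an all-points (or
#' event-amplitude) histogram:
#' \deqn{N(i) = \sum_{j=1}^{n} a_j \exp\!\left[-\frac{(i - jq)^2}{2jb}\right]}
#' so component \eqn{j} has mean \eqn{jq} and variance \eqn{jb}
#' (level-proportional broadening).
#'
#' @slot q quantal unit (signed; pA or nM).
#' @slot b variance parameter of the elementary level (units squared).
#' @slot a nonnegative component amplitudes a_1..a_n.
#' @slot nComponents number of open-level components fitted.
#' @slot residual residual sum of squares.
#' @slot baselinePeak fitted closed-peak parameters (a0, mu0, sd0), or NAs.
#' @export
setClass("QuantalFit",
  representation(q = "numeric", b = "numeric", a = "numeric",
                 nComponents = "integer", residual = "numeric",
                 baselinePeak = "numeric"))

setValidity("QuantalFit", function(object) {
  msg <- character()
  if (object@nComponents < 1L) msg <- c(msg, "nComponents must be >= 1")
  if (length(object@a) != object@nComponents)
    msg <- c(msg, "length(a) must equal nComponents")
  if (any(object@a < 0)) msg <- c(msg, "component amplitudes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Coupling-coefficient fit
#'
#' Result of maximum-likelihood estimation of the coupled Markov-chain model
#' on one record.  A site is called coupled when \code{kappaHat > threshold}
#' (default 0.1).
#'
#' @slot kappaHat estimated coupling coefficient in [0, 1].
#' @slot pOpenHat,pCloseHat estimated per-frame gating probabilities.
#' @slot logLik maximized log-likelihood.
#' @slot coupled logical classification (kappaHat > threshold).
#' @slot nChannels channel count N supplied by the caller.
#' @slot threshold classification cutoff.
#' @slot flags character vector of fit diagnostics (e.g. "no transitions").
#' @export
setClass("CouplingFit",
  representation(kappaHat = "numeric", pOpenHat = "numeric",
                 pCloseHat = "numeric", logLik = "numeric",
                 coupled = "logical", nChannels = "integer",
                 threshold = "numeric", flags = "character"))

setValidity("CouplingFit", function(object) {
  msg <- character()
  if (object@kappaHat < 0 || object@kappaHat > 1)
    msg <- c(msg, "kappaHat must lie in [0, 1]")
  if (!identical(object@coupled, object@kappaHat > object@threshold))
    msg <- c(msg, "coupled must equal kappaHat > threshold")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Imaging containers
## ---------------------------------------------------------------------------

#' Image stack (movie)
#'
#' @slot data numeric array, rows x cols x frames; nonnegative intensities.
#' @slot pixelSize pixel size in nm.
#' @slot dt frame interval in seconds.
#' @export
setClass("ImageStack",
  representation(data = "array", pixelSize = "numeric", dt = "numeric"))

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a rows x cols x frames array")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (length(msg)) msg else TRUE
})

#' @param data rows x cols x frames numeric array.
#' @param pixelSize pixel size (nm).
#' @param dt frame interval (s).
#' @rdname ImageStack-class
#' @export
imageStack <- function(data, pixelSize, dt) {
  new("ImageStack", data = data, pixelSize = as.numeric(pixelSize),
      dt = as.numeric(dt))
}

#' Photobleaching step fit
#'
#' Piecewise-constant description of one ROI z-profile: the number of
#' downward bleaching steps, the frame of each step and its (negative)
#' amplitude.
#'
#' @slot nSteps number of retained downward steps.
#' @slot stepFrames frame index of each step (strictly increasing).
#' @slot stepAmplitudes level change at each step (negative, AU).
#' @slot residual residual sum of squares of the piecewise-constant fit.
#' @slot levels fitted segment levels (length nSteps + 1).
#' @slot flags diagnostics ("max_steps_reached" when the cap was hit).
#' @export
setClass("StepFit",
  representation(nSteps = "integer", stepFrames = "integer",
                 stepAmplitudes = "numeric", residual = "numeric",
                 levels = "numeric", flags = "character"))

setValidity("StepFit", function(object) {
  msg <- character()
  if (object@nSteps != length(object@stepFrames) ||
      object@nSteps != length(object@stepAmplitudes))
    msg <- c(msg, "stepFrames/stepAmplitudes must have length nSteps")
  if (object@nSteps > 1L && any(diff(object@stepFrames) <= 0L))
    msg <- c(msg, "stepFrames must be strictly increasing")
  if (any(object@stepAmplitudes >= 0))
    msg <- c(msg, "step amplitudes must be negative")
  if (length(msg)) msg else TRUE
})

#' Single-molecule localization table
#'
#' @slot coords data.frame with columns x, y (nm), photons and frame.
#' @slot dlr diffraction-limited resolution used for precision (nm; NA if
#'   unknown).
#' @export
setClass("LocalizationSet",
  representation(coords = "data.frame", dlr = "numeric"))

setValidity("LocalizationSet", function(object) {
  need <- c("x", "y", "photons")
  if (!all(need %in% names(object@coords)))
    return("coords must contain columns x, y, photons")
  if (nrow(object@coords) && any(object@coords$photons <= 0))
    return("photon counts must be positive")
  TRUE
})

#' @param coords data.frame with x, y, photons (and optionally frame).
#' @param dlr diffraction-limited resolution (nm).
#' @rdname LocalizationSet-class
#' @export
localizationSet <- function(coords, dlr = NA_real_) {
  coords <- as.data.frame(coords)
  if (is.null(coords$frame)) coords$frame <- seq_len(nrow(coords))
  new("LocalizationSet", coords = coords, dlr = as.numeric(dlr))
}

#' Cluster statistics from binary-mask segmentation
#'
#' @slot areas per-cluster areas (nm^2).
#' @slot meanArea mean cluster area (nm^2).
#' @slot semArea SEM of cluster area (nm^2).
#' @slot density clusters per um^2 of imaged area.
#' @slot nClusters number of clusters.
#' @slot labels integer label mask (rows x cols) of the rendered image.
#' @export
setClass("ClusterStats",
  representation(areas = "numeric", meanArea = "numeric", semArea = "numeric",
                 density = "numeric", nClusters = "integer",
                 labels = "matrix"))

setValidity("ClusterStats", function(object) {
  if (object@nClusters != length(object@areas))
    return("nClusters must equal length(areas)")
  TRUE
})

## ---------------------------------------------------------------------------
## Sparklet site
## ---------------------------------------------------------------------------

#' Sparklet site summary
#'
#' Event list and activity measures for one sparklet site.  Activity nPs is
#' the time-averaged occupancy (the optical analog of NPo); Ps is the
#' fraction of frames with at least one open channel.
#'
#' @slot events data.frame (start_frame, end_frame, level, mean_amplitude).
#' @slot nps time-averaged occupancy, >= 0.
#' @slot nLevels maximum quantal level observed.
#' @slot activeFraction Ps, fraction of frames with occupancy >= 1.
#' @slot siteId site label.
#' @export
setClass("SparkletSite",
  representation(events = "data.frame", nps = "numeric", nLevels = "integer",
                 activeFraction = "numeric", siteId = "character"))

setValidity("SparkletSite", function(object) {
  msg <- character()
  if ((object@nps == 0) != (nrow(object@events) == 0L))
    msg <- c(msg, "nps must be zero exactly when there are no events")
  if (object@activeFraction < 0 || object@activeFraction > 1)
    msg <- c(msg, "activeFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Whole-cell fit result
## ---------------------------------------------------------------------------

#' Boltzmann activation fit
#'
#' Fit of the normalized conductance-voltage relation to
#' \eqn{g(V) = 1 / (1 + \exp((V_{1/2} - V)/k))}.
#'
#' @slot vHalf half-activation voltage (mV).
#' @slot slopeK slope factor (mV, > 0 for activation).
#' @slot residual residual sum of squares.
#' @export
setClass("BoltzmannFit",
  representation(vHalf = "numeric", slopeK = "numeric", residual = "numeric"))

setValidity("BoltzmannFit", function(object) {
  if (object@slopeK <= 0) return("slopeK must be positive") else TRUE
})
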