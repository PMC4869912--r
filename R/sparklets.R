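## Sparklet detection, nPs activity scoring, quantal amplitude fitting,
## density, and fluorescence-to-[Ca2+] conversion.

## Histogram-mode baseline with 1 nM bins: robust when the site is active
## and the mean is above rest.
.autoBaseline <- function(x, binWidth = 1) {
  idx <- round(x / binWidth)
  tab <- table(idx)
  as.numeric(names(tab)[which.max(tab)]) * binWidth
}

#' Detect sparklet events in a [Ca2+] trace
#'
#' An event is a maximal run of frames with signal at least
#' \code{baseline + q/2} lasting at least \code{minDurationFrames} (default
#' 2 frames, 20 ms at 100 Hz: rejects single-frame noise while keeping
#' brief quantal events).  Each frame's level is
#' \code{round((x - baseline)/q)}; the event level is the maximum frame
#' level and the event amplitude is the mean signal, minus baseline, over
#' the frames at that maximum level.
#'
#' @param trace a [CalciumTrace-class] with >= 10 frames.
#' @param q quantal amplitude (nM, > 0; the analysis constant is 38 nM).
#' @param baseline resting [Ca2+] (nM) or "auto" (histogram mode, 1 nM
#'   bins).
#' @param minDurationFrames minimum event duration in frames.
#' @return data.frame with columns start_frame, end_frame, level,
#'   mean_amplitude (nM above baseline).
#' @export
detectEvents <- function(trace, q = 38, baseline = "auto",
                         minDurationFrames = 2) {
  stopifnot(is(trace, "CalciumTrace"))
  if (q <= 0) stop("q must be positive for sparklet records")
  x <- trace@values
  if (length(x) < 10) stop("trace must have at least 10 frames")
  if (identical(baseline, "auto")) baseline <- .autoBaseline(x)

  active <- x >= baseline + q / 2
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minDurationFrames
  if (!any(keep))
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      level = integer(), mean_amplitude = numeric()))
  ev <- data.frame(start_frame = starts[keep], end_frame = ends[keep])
  lev <- integer(nrow(ev)); amp <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    seg <- x[ev$start_frame[i]:ev$end_frame[i]]
    k <- pmax(round((seg - baseline) / q), 1)
    lev[i] <- max(k)
    atMax <- seg[k == lev[i]]
    amp[i] <- mean(atMax) - baseline
  }
  ev$level <- lev
  ev$mean_amplitude <- amp
  ev
}

#' Sparklet-site activity (nPs)
#'
#' Quantizes the trace and scores the site: nPs is the time-averaged
#' occupancy \eqn{\sum_t k_t / T} (the optical analog of NPo), Ps the
#' fraction of frames with at least one open channel, and nLevels the
#' maximum quantal level observed.
#'
#' @inheritParams detectEvents
#' @param nChannels maximum level for quantization (default 7, the largest
#'   level count seen in neuronal records).
#' @return a [SparkletSite-class].
#' @export
siteNps <- function(trace, q = 38, baseline = "auto", nChannels = 7,
                    minDurationFrames = 2) {
  stopifnot(is(trace, "CalciumTrace"))
  if (q <= 0) stop("q must be positive")
  x <- trace@values
  if (identical(baseline, "auto")) baseline <- .autoBaseline(x)
  events <- detectEvents(trace, q = q, baseline = baseline,
                         minDurationFrames = minDurationFrames)
  occ <- quantizeTrace(trace, q = q, baseline = baseline,
                       nChannels = nChannels)
  k <- occ@k
  if (nrow(events) == 0L) k[] <- 0L  # no accepted events: quiet site
  new("SparkletSite", events = events,
      nps = sum(k) / length(k),
      nLevels = as.integer(max(c(0L, events$level))),
      activeFraction = mean(k >= 1L),
      siteId = trace@siteId)
}

#' Quantal amplitude from an event-amplitude histogram
#'
#' Builds the amplitude histogram of detected events and fits the same
#' multicomponent Gaussian quantal model used for single-channel all-points
#' histograms ([fitQuantalGaussians()]), in nM units.
#'
#' @param events data.frame of events (from [detectEvents()], possibly
#'   pooled over sites) with a mean_amplitude column, or a numeric vector
#'   of amplitudes.  At least 30 events are required.
#' @param binWidth histogram bin width in nM (default 4).
#' @param nComponents quantal components to fit (default 2).
#' @return a [QuantalFit-class]; \code{quantalUnit()} is the elementary
#'   sparklet amplitude in nM.
#' @export
fitEventAmplitudes <- function(events, binWidth = 4, nComponents = 2) {
  amps <- if (is.data.frame(events)) events$mean_amplitude
          else as.numeric(events)
  if (length(amps) < 30)
    stop("need at least 30 events for an amplitude fit (got ",
         length(amps), ")")
  h <- allPointsHistogram(amps, binWidth = binWidth)
  fitQuantalGaussians(h, nComponents = nComponents, qInit = "auto",
                      fitBaseline = FALSE)
}

#' Sparklet site density
#'
#' @param sites list of [SparkletSite-class] (or data.frames of events);
#'   only sites with at least one event are counted.
#' @param footprintArea imaged membrane area in um^2 (> 0).
#' @return active sites per um^2.
#' @export
sparkletDensity <- function(sites, footprintArea) {
  if (footprintArea <= 0) stop("footprintArea must be positive")
  nActive <- sum(vapply(sites, function(s) {
    ev <- if (is(s, "SparkletSite")) s@events else s
    nrow(ev) > 0L
  }, logical(1)))
  nActive / footprintArea
}

#' Convert a fluorescence trace to [Ca2+]
#'
#' Two calibrations: \code{linear}, \eqn{[Ca] = scale (F - F_{rest}) +
#' Ca_{rest}}; and \code{saturating} (single-site dye binding),
#' \eqn{[Ca] = K_d (F - F_{min}) / (F_{max} - F)}.
#'
#' @param fTrace a [SignalTrace-class] (AU) or numeric vector.
#' @param mode "linear" or "saturating".
#' @param params named list of calibration constants: linear needs
#'   \code{scale}, \code{fRest}, \code{caRest}; saturating needs \code{kd},
#'   \code{fMin}, \code{fMax}.
#' @param dt sampling interval, required when fTrace is a bare vector.
#' @return a [CalciumTrace-class] in nM.
#' @export
fluorescenceToCa <- function(fTrace, mode = c("linear", "saturating"),
                             params, dt = NULL) {
  mode <- match.arg(mode)
  x <- if (is(fTrace, "SignalTrace")) fTrace@values else as.numeric(fTrace)
  if (is(fTrace, "SignalTrace")) dt <- fTrace@dt
  if (is.null(dt)) stop("dt required for vector input")
  need <- if (mode == "linear") c("scale", "fRest", "caRest")
          else c("kd", "fMin", "fMax")
  if (!all(need %in% names(params)))
    stop("calibration params incomplete; need ",
         paste(need, collapse = ", "))
  ca <- if (mode == "linear") {
    params$scale * (x - params$fRest) + params$caRest
  } else {
    if (any(x >= params$fMax))
      stop("fluorescence at or above fMax; saturating calibration invalid")
    params$kd * (x - params$fMin) / (params$fMax - x)
  }
  calciumTrace(ca, dt,
               siteId = if (is(fTrace, "SignalTrace")) fTrace@siteId else "")
}
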