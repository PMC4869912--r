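## Named presets anchored to the biophysical constants of CaV1.3 splice
## variants, plus seed plumbing.  All randomness in the package flows from a
## single top-level seed through named substreams so adding one generator
## call does not perturb another.

#' Derive a reproducible substream seed
#'
#' Hashes a (seed, name) pair into an integer below 2^31 so each generator
#' draws from its own named stream of the top-level seed.
#'
#' @param seed top-level integer seed.
#' @param name character substream label.
#' @return integer seed in [1, 2^31 - 2].
#' @export
substreamSeed <- function(seed, name) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- as.numeric(seed) %% m
  for (code in utf8ToInt(as.character(name)))
    s <- (s * 31 + code) %% m
  as.integer(max(1, s))
}

## Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## ---------------------------------------------------------------------------
## Gating presets
## ---------------------------------------------------------------------------

.GATING_PRESETS <- list(
  # Sparklet-site gating at 100 Hz imaging.  kappa values are the mean
  # coupling coefficients measured for the short (0.21) and long (0.08)
  # C-terminal splice variants; 2 channels per site matches the 1-3 quantal
  # levels typical of expressed-cell records.  pOpen/pClose give brief
  # (~30 ms) openings at low resting activity.
  cav13s_sparklet = list(nChannels = 2L, pOpen = 0.03, pClose = 0.3,
                         kappa = 0.21),
  cav13l_sparklet = list(nChannels = 2L, pOpen = 0.03, pClose = 0.3,
                         kappa = 0.08),
  independent_sparklet = list(nChannels = 2L, pOpen = 0.03, pClose = 0.3,
                              kappa = 0),
  # Depolarization-boosted activity (higher opening rate, same kinetics).
  cav13s_sparklet_depol = list(nChannels = 2L, pOpen = 0.09, pClose = 0.3,
                               kappa = 0.21),
  # Single-channel gating at 10 kHz with the dihydropyridine agonist
  # BayK-8644 in the pipette: long (~20 ms) openings, Po = 0.3.
  single_channel_bayk = list(nChannels = 1L, pOpen = 0.3 / 0.7 * 0.005,
                             pClose = 0.005, kappa = 0)
)

#' Named gating presets
#'
#' Returns a [CoupledGatingModel-class] for a named preset:
#' \describe{
#'   \item{cav13s_sparklet}{2 channels, kappa = 0.21 (CaV1.3S sites).}
#'   \item{cav13l_sparklet}{2 channels, kappa = 0.08 (CaV1.3L sites).}
#'   \item{independent_sparklet}{2 channels, kappa = 0.}
#'   \item{cav13s_sparklet_depol}{as cav13s_sparklet with 3x opening rate.}
#'   \item{single_channel_bayk}{1 channel, Po = 0.3, 20 ms mean open time at
#'     10 kHz sampling.}
#' }
#'
#' @param name preset name.
#' @return a [CoupledGatingModel-class].
#' @export
gatingPreset <- function(name) {
  p <- .GATING_PRESETS[[name]]
  if (is.null(p))
    stop("unknown gating preset '", name, "'; available: ",
         paste(names(.GATING_PRESETS), collapse = ", "))
  coupledGatingModel(p$nChannels, p$pOpen, p$pClose, p$kappa)
}

## ---------------------------------------------------------------------------
## Signal presets
## ---------------------------------------------------------------------------

.SIGNAL_PRESETS <- list(
  # Sparklets at 100 Hz: elementary amplitude 38 nM on a ~100 nM resting
  # [Ca2+]i, 8 nM measurement noise.
  sparklet_default = list(quantalAmplitude = 38, baseline = 100,
                          noiseSd = 8, dt = 0.01, units = "nM"),
  # Cell-attached unitary currents at -30 mV, 10 kHz sampling.
  cav13s_ca_m30 = list(quantalAmplitude = -0.49, baseline = 0,
                       noiseSd = 0.15, dt = 1e-4, units = "pA"),
  cav13l_ca_m30 = list(quantalAmplitude = -0.48, baseline = 0,
                       noiseSd = 0.15, dt = 1e-4, units = "pA"),
  cav13s_ba_m30 = list(quantalAmplitude = -1.10, baseline = 0,
                       noiseSd = 0.2, dt = 1e-4, units = "pA"),
  cav13l_ba_m30 = list(quantalAmplitude = -1.14, baseline = 0,
                       noiseSd = 0.2, dt = 1e-4, units = "pA")
)

#' Signal presets and constructor
#'
#' A signal preset maps channel occupancy to an observable trace:
#' \code{value = baseline + quantalAmplitude * k + N(0, noiseSd)}.  Named
#' presets: \code{sparklet_default} (38 nM quanta on a 100 nM baseline,
#' 8 nM noise, 100 Hz), \code{cav13s_ca_m30} (-0.49 pA),
#' \code{cav13l_ca_m30} (-0.48 pA), \code{cav13s_ba_m30} (-1.10 pA),
#' \code{cav13l_ba_m30} (-1.14 pA) all at 10 kHz.
#'
#' @param name preset name, or NULL to build a custom preset.
#' @param quantalAmplitude signal increment per open channel (nonzero; nM or
#'   pA).
#' @param baseline resting signal.
#' @param noiseSd additive Gaussian noise SD (>= 0).
#' @param dt sampling interval in seconds (> 0).
#' @param units unit label.
#' @return a list with fields quantalAmplitude, baseline, noiseSd, dt,
#'   units, name.
#' @export
signalPreset <- function(name = NULL, quantalAmplitude = NULL,
                         baseline = NULL, noiseSd = NULL, dt = NULL,
                         units = NULL) {
  if (!is.null(name)) {
    p <- .SIGNAL_PRESETS[[name]]
    if (is.null(p))
      stop("unknown signal preset '", name, "'; available: ",
           paste(names(.SIGNAL_PRESETS), collapse = ", "))
    p$name <- name
  } else {
    p <- list(quantalAmplitude = quantalAmplitude, baseline = baseline,
              noiseSd = noiseSd, dt = dt,
              units = if (is.null(units)) "AU" else units, name = "custom")
  }
  # overrides
  if (!is.null(quantalAmplitude)) p$quantalAmplitude <- quantalAmplitude
  if (!is.null(baseline)) p$baseline <- baseline
  if (!is.null(noiseSd)) p$noiseSd <- noiseSd
  if (!is.null(dt)) p$dt <- dt
  for (f in c("quantalAmplitude", "baseline", "noiseSd", "dt"))
    if (is.null(p[[f]]) || !is.numeric(p[[f]]) || is.na(p[[f]]))
      stop("signal preset field '", f, "' is missing or not numeric")
  if (p$quantalAmplitude == 0)
    stop("signal preset field 'quantalAmplitude' must be nonzero")
  if (p$noiseSd < 0) stop("signal preset field 'noiseSd' must be >= 0")
  if (p$dt <= 0) stop("signal preset field 'dt' must be positive")
  p
}

## ---------------------------------------------------------------------------
## Whole-cell kinetic presets
## ---------------------------------------------------------------------------

.WHOLECELL_PRESETS <- list(
  # Activation time constants at -10 mV for the short (1.17 ms) and long
  # (1.60 ms) variants; inactivation set slow (10 s) so the activation phase
  # dominates the 300 ms pulse.
  cav13s_act = list(tauAct = 1.17, tauInact = 1e4, eRev = 54),
  cav13l_act = list(tauAct = 1.60, tauInact = 1e4, eRev = 51),
  # CDI-grade presets: fast inactivation with Ca2+, slow with Ba2+.
  cav13s_cdi_ca = list(tauAct = 1.17, tauInact = 60, eRev = 54),
  cav13s_cdi_ba = list(tauAct = 1.17, tauInact = 800, eRev = 65)
)

#' Whole-cell kinetic presets
#'
#' Activation/inactivation time constants (ms) and reversal potentials (mV)
#' for [makeWholeCellTrace()].  `cav13s_act` / `cav13l_act` carry the
#' measured activation constants 1.17 and 1.60 ms with negligible
#' inactivation; the `cdi` presets pair fast Ca2+-dependent inactivation
#' with slow Ba2+ decay.
#'
#' @param name preset name.
#' @return list(tauAct, tauInact, eRev, name).
#' @export
wholeCellPreset <- function(name) {
  p <- .WHOLECELL_PRESETS[[name]]
  if (is.null(p))
    stop("unknown whole-cell preset '", name, "'; available: ",
         paste(names(.WHOLECELL_PRESETS), collapse = ", "))
  p$name <- name
  p
}

## ---------------------------------------------------------------------------
## Bleaching and emitter-cloud presets
## ---------------------------------------------------------------------------

#' Photobleaching staircase preset
#'
#' Parameters for [makeBleachStack()].  `nFluorophores` may be a single
#' count or a distribution spec (see [distributionSpec()]); the default
#' mixture mimics clusters of GFP-tagged channels with a mean near 8.
#'
#' @param nFluorophores count or distribution spec for fluorophores per spot.
#' @param stepAmplitude intensity drop per bleaching event (AU).
#' @param bleachRate per-frame bleaching hazard in (0, 1].
#' @param noiseSd additive Gaussian noise SD (AU).
#' @param nFrames frames in the movie (default 2000 at 30 Hz).
#' @param background offset intensity (AU).
#' @param psfSigma PSF width (px) used to render each spot.
#' @param forcedBleachFrames optional list of integer vectors overriding the
#'   random bleach times (deterministic staircases for tests).
#' @return validated preset list.
#' @export
bleachPreset <- function(nFluorophores = distributionSpec("poisson",
                                                          lambda = 8,
                                                          min = 1),
                         stepAmplitude = 100, bleachRate = 0.002,
                         noiseSd = 0, nFrames = 2000, background = 50,
                         psfSigma = 1.3, forcedBleachFrames = NULL) {
  if (is.numeric(nFluorophores) && any(nFluorophores < 0))
    stop("bleach preset field 'nFluorophores' must be >= 0")
  if (bleachRate <= 0 || bleachRate > 1)
    stop("bleach preset field 'bleachRate' must lie in (0, 1]")
  if (noiseSd < 0) stop("bleach preset field 'noiseSd' must be >= 0")
  if (nFrames < 2) stop("bleach preset field 'nFrames' must be >= 2")
  list(nFluorophores = nFluorophores, stepAmplitude = stepAmplitude,
       bleachRate = bleachRate, noiseSd = noiseSd, nFrames = nFrames,
       background = background, psfSigma = psfSigma,
       forcedBleachFrames = forcedBleachFrames)
}

#' Emitter point-cloud preset
#'
#' Parameters for [makeLocalizations()].  Localization error per event is
#' isotropic Gaussian with sigma = dlr / sqrt(photons), the standard
#' photon-budget precision law.
#'
#' @param nClusters number of clusters in the field.
#' @param channelsPerCluster count or distribution spec for fluorophores per
#'   cluster (default Poisson mean 8, min 1).
#' @param clusterRadius disk radius (nm) containing the fluorophores.
#' @param localizationsPerFluorophore count or spec of switching events per
#'   fluorophore.
#' @param photonsPerLocalization count or spec; default lognormal with
#'   median 1900 photons (heavy right tail typical of switching events).
#' @param dlr diffraction-limited resolution (nm); default 710, the center
#'   of the 660-760 nm detection band.
#' @param fieldSize field side length (nm).
#' @return validated preset list.
#' @export
emitterCloudPreset <- function(nClusters = 20,
                               channelsPerCluster =
                                 distributionSpec("poisson", lambda = 8,
                                                  min = 1),
                               clusterRadius = 30,
                               localizationsPerFluorophore =
                                 distributionSpec("poisson", lambda = 20,
                                                  min = 1),
                               photonsPerLocalization =
                                 distributionSpec("lognormal",
                                                  meanlog = log(1900),
                                                  sdlog = 0.3),
                               dlr = 710, fieldSize = 20000) {
  if (nClusters < 0) stop("emitter preset field 'nClusters' must be >= 0")
  if (dlr <= 0) stop("emitter preset field 'dlr' must be positive")
  if (clusterRadius < 0 || fieldSize <= 0)
    stop("emitter preset fields 'clusterRadius'/'fieldSize' invalid")
  list(nClusters = nClusters, channelsPerCluster = channelsPerCluster,
       clusterRadius = clusterRadius,
       localizationsPerFluorophore = localizationsPerFluorophore,
       photonsPerLocalization = photonsPerLocalization,
       dlr = dlr, fieldSize = fieldSize)
}

#' Distribution specifications for count/photon draws
#'
#' A tiny declarative spec for the generators' random counts:
#' \code{distributionSpec("fixed", value = 3)},
#' \code{distributionSpec("poisson", lambda = 8, min = 1)},
#' \code{distributionSpec("categorical", values = 1:3, probs = c(.2,.5,.3))},
#' \code{distributionSpec("lognormal", meanlog = , sdlog = )}.
#'
#' @param dist one of "fixed", "poisson", "categorical", "lognormal".
#' @param ... distribution parameters (see above).
#' @return spec list consumed by the generators.
#' @export
distributionSpec <- function(dist = c("fixed", "poisson", "categorical",
                                      "lognormal"), ...) {
  dist <- match.arg(dist)
  spec <- c(list(dist = dist), list(...))
  if (dist == "fixed" && is.null(spec$value))
    stop("fixed spec needs 'value'")
  if (dist == "poisson" && is.null(spec$lambda))
    stop("poisson spec needs 'lambda'")
  if (dist == "categorical" &&
      (is.null(spec$values) || is.null(spec$probs) ||
       length(spec$values) != length(spec$probs)))
    stop("categorical spec needs matching 'values' and 'probs'")
  if (dist == "lognormal" && (is.null(spec$meanlog) || is.null(spec$sdlog)))
    stop("lognormal spec needs 'meanlog' and 'sdlog'")
  spec
}

## Draw n values from a spec (or a plain number = fixed).
.drawSpec <- function(spec, n) {
  if (is.numeric(spec)) return(rep(spec, length.out = n))
  switch(spec$dist,
    fixed = rep(spec$value, n),
    poisson = {
      x <- rpois(n, spec$lambda)
      if (!is.null(spec$min)) x <- pmax(x, spec$min)
      x
    },
    categorical = spec$values[sample.int(length(spec$values), n,
                                         replace = TRUE, prob = spec$probs)],
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    stop("unknown distribution spec"))
}
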