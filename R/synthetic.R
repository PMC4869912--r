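## Synthetic-data generators.  Every generator returns the ground truth
## needed to score downstream recovery, and is bit-reproducible given its
## seed (named substreams keep generators independent of one another).

#' Simulate a sparklet [Ca2+] trace with known occupancy
#'
#' Simulates the hidden occupancy of a coupled gating model and maps it to a
#' fluorescence-derived [Ca2+] trace:
#' \code{value_t = baseline + quantalAmplitude * k_t + N(0, noiseSd)}.
#'
#' @param gating a [CoupledGatingModel-class] (e.g. from [gatingPreset()]).
#' @param signal a signal preset from [signalPreset()].
#' @param nFrames number of frames (>= 2).
#' @param seed integer seed.
#' @param siteId optional site label.
#' @return list with elements \code{trace} ([CalciumTrace-class]) and
#'   \code{occupancy} ([OccupancyTrace-class], the ground truth).
#' @examples
#' sim <- makeSparkletTrace(gatingPreset("cav13s_sparklet"),
#'                          signalPreset("sparklet_default"), 2000, seed = 1)
#' sim$trace
#' @export
makeSparkletTrace <- function(gating, signal, nFrames, seed, siteId = "") {
  stopifnot(is(gating, "CoupledGatingModel"))
  if (nFrames < 2) stop("nFrames must be >= 2")
  occ <- simulateOccupancy(gating, nFrames,
                           seed = substreamSeed(seed, "occupancy"),
                           dt = signal$dt)
  noise <- if (signal$noiseSd > 0)
    withSeed(substreamSeed(seed, "noise"),
             rnorm(nFrames, 0, signal$noiseSd))
  else rep(0, nFrames)
  vals <- signal$baseline + signal$quantalAmplitude * occ@k + noise
  list(trace = calciumTrace(vals, signal$dt, siteId = siteId),
       occupancy = occ)
}

#' Simulate single-channel current sweeps
#'
#' Each sweep is an independent realization of the gating chain mapped to
#' current: \code{baseline + iUnitary * k_t + noise}.  Multi-channel patches
#' are allowed by passing a model with nChannels > 1.
#'
#' @param gating a [CoupledGatingModel-class]; typically nChannels = 1.
#' @param signal a [signalPreset()] whose quantalAmplitude is the unitary
#'   current (pA, negative for inward).
#' @param nSweeps number of sweeps.
#' @param sweepFrames frames per sweep (>= 2).
#' @param seed integer seed.
#' @param voltage test potential (mV), stored with the sweeps.
#' @return list with \code{sweeps} ([SweepSet-class]) and \code{occupancy}
#'   (list of [OccupancyTrace-class] ground truths).
#' @export
makeSingleChannelSweeps <- function(gating, signal, nSweeps, sweepFrames,
                                    seed, voltage = -30) {
  stopifnot(is(gating, "CoupledGatingModel"))
  if (sweepFrames < 2) stop("sweepFrames must be >= 2")
  sweeps <- matrix(0, nrow = sweepFrames, ncol = nSweeps)
  occs <- vector("list", nSweeps)
  for (s in seq_len(nSweeps)) {
    occ <- simulateOccupancy(
      gating, sweepFrames,
      seed = substreamSeed(seed, paste0("sweep_occ_", s)),
      dt = signal$dt)
    noise <- if (signal$noiseSd > 0)
      withSeed(substreamSeed(seed, paste0("sweep_noise_", s)),
               rnorm(sweepFrames, 0, signal$noiseSd))
    else rep(0, sweepFrames)
    sweeps[, s] <- signal$baseline + signal$quantalAmplitude * occ@k + noise
    occs[[s]] <- occ
  }
  list(sweeps = sweepSet(sweeps, signal$dt, voltage = voltage),
       occupancy = occs)
}

#' Simulate a whole-cell current trace
#'
#' Deterministic kinetic model plus optional noise:
#' \deqn{I(t) = g_{max} (V - E_{rev}) (1 - e^{-t/\tau_{act}})
#'       e^{-t/\tau_{inact}} + \epsilon_t}
#' with \eqn{g_{max}} in nS, voltages in mV (so current is in pA) and time
#' constants in ms.  \code{v = eRev} is valid and yields a zero
#' deterministic part.
#'
#' @param gMax maximal conductance (nS).
#' @param v test potential (mV).
#' @param eRev reversal potential (mV); +54 for Ca2+ and +65 for Ba2+ are
#'   the CaV1.3S defaults carried by [wholeCellPreset()].
#' @param tauAct,tauInact activation / inactivation time constants (ms, > 0).
#' @param duration pulse length (ms).
#' @param dt sample interval (ms).
#' @param noiseSd additive Gaussian noise SD (pA).
#' @param seed seed, required when noiseSd > 0.
#' @return a [CurrentTrace-class]; time runs from 0 to duration.
#' @export
makeWholeCellTrace <- function(gMax, v, eRev = 54, tauAct = 1.17,
                               tauInact = 1e4, duration = 300, dt = 0.05,
                               noiseSd = 0, seed = NULL) {
  if (tauAct <= 0 || tauInact <= 0)
    stop("tauAct and tauInact must be positive")
  t <- seq(0, duration, by = dt)
  i <- gMax * (v - eRev) * (1 - exp(-t / tauAct)) * exp(-t / tauInact)
  if (noiseSd > 0) {
    if (is.null(seed)) stop("seed required when noiseSd > 0")
    i <- i + withSeed(substreamSeed(seed, "wholecell_noise"),
                      rnorm(length(t), 0, noiseSd))
  }
  currentTrace(i, dt / 1000)
}

#' Simulate a step-photobleaching movie
#'
#' Renders \code{nSpots} 2D-Gaussian spots whose amplitudes follow
#' staircases: each fluorophore bleaches at an independent geometric
#' (memoryless, per-frame hazard) time, dropping the spot amplitude by
#' \code{stepAmplitude}.  Spots are placed on a grid at least 8 px apart.
#'
#' @param preset a [bleachPreset()].
#' @param nSpots number of spots.
#' @param imageSize image side (px).
#' @param seed integer seed.
#' @param pixelSize pixel size (nm), default 100.
#' @return list with \code{stack} ([ImageStack-class]), \code{spots}
#'   (data.frame row, col, nFluorophores) and \code{bleachFrames} (list of
#'   integer bleach times per spot).
#' @export
makeBleachStack <- function(preset, nSpots, imageSize = 64, seed = 1,
                            pixelSize = 100) {
  spacing <- 8L
  margin <- 5L
  gridPos <- seq(margin + 1L, imageSize - margin, by = spacing)
  capacity <- length(gridPos) ^ 2
  if (nSpots > capacity)
    stop("too many spots for the field: capacity is ", capacity)
  cells <- expand.grid(row = gridPos, col = gridPos)[seq_len(nSpots), ]

  nF <- preset$nFrames
  out <- withSeed(substreamSeed(seed, "bleach"), {
    nFluor <- as.integer(.drawSpec(preset$nFluorophores, nSpots))
    bleachFrames <- vector("list", nSpots)
    for (sp in seq_len(nSpots)) {
      if (!is.null(preset$forcedBleachFrames)) {
        bleachFrames[[sp]] <- as.integer(preset$forcedBleachFrames[[sp]])
        nFluor[sp] <- length(bleachFrames[[sp]])
      } else if (nFluor[sp] > 0L) {
        # geometric per-frame hazard, capped at the movie end
        bf <- 1L + stats::rgeom(nFluor[sp], preset$bleachRate)
        bleachFrames[[sp]] <- sort(pmin(bf, nF))
      } else bleachFrames[[sp]] <- integer()
    }
    noise <- if (preset$noiseSd > 0)
      array(rnorm(imageSize * imageSize * nF, 0, preset$noiseSd),
            dim = c(imageSize, imageSize, nF))
    else 0
    list(nFluor = nFluor, bleachFrames = bleachFrames, noise = noise)
  })

  # per-spot amplitude staircase: number of unbleached fluorophores x step
  amps <- matrix(0, nrow = nSpots, ncol = nF)
  for (sp in seq_len(nSpots)) {
    alive <- rep(out$nFluor[sp], nF)
    for (bf in out$bleachFrames[[sp]])
      if (bf < nF) alive[(bf + 1L):nF] <- alive[(bf + 1L):nF] - 1L
    amps[sp, ] <- alive * preset$stepAmplitude
  }

  # render: background + sum of Gaussians
  s2 <- 2 * preset$psfSigma ^ 2
  halfw <- ceiling(3 * preset$psfSigma)
  stack <- array(preset$background, dim = c(imageSize, imageSize, nF))
  for (sp in seq_len(nSpots)) {
    r0 <- cells$row[sp]; c0 <- cells$col[sp]
    rows <- max(1L, r0 - halfw):min(imageSize, r0 + halfw)
    cols <- max(1L, c0 - halfw):min(imageSize, c0 + halfw)
    g <- outer(exp(-(rows - r0) ^ 2 / s2), exp(-(cols - c0) ^ 2 / s2))
    for (f in seq_len(nF))
      if (amps[sp, f] > 0)
        stack[rows, cols, f] <- stack[rows, cols, f] + amps[sp, f] * g
  }
  if (!identical(out$noise, 0)) stack <- stack + out$noise
  stack <- pmax(stack, 0)

  list(stack = imageStack(stack, pixelSize = pixelSize, dt = 1 / 30),
       spots = data.frame(row = cells$row, col = cells$col,
                          nFluorophores = out$nFluor),
       bleachFrames = out$bleachFrames)
}

#' Simulate a clustered single-molecule localization table
#'
#' Plants cluster centers in the field, scatters fluorophores uniformly in a
#' disk of \code{clusterRadius} around each center, and emits per-fluorophore
#' localizations displaced by isotropic Gaussian error with
#' sigma = dlr / sqrt(photons drawn for that event).
#'
#' @param preset an [emitterCloudPreset()].
#' @param seed integer seed.
#' @return list with \code{locs} ([LocalizationSet-class]),
#'   \code{centers} (data.frame of true cluster centers), and \code{truth}
#'   (data.frame of true emitter positions per localization).
#' @export
makeLocalizations <- function(preset, seed = 1) {
  withSeed(substreamSeed(seed, "localizations"), {
    n <- preset$nClusters
    margin <- preset$clusterRadius + 4 * preset$dlr / sqrt(100)
    if (n > 0 && preset$fieldSize < 4 * margin)
      warning("field may be too small; clusters can merge")
    centers <- data.frame(
      cluster = seq_len(n),
      x = runif(n, margin, preset$fieldSize - margin),
      y = runif(n, margin, preset$fieldSize - margin))
    rows <- list()
    truthRows <- list()
    for (cl in seq_len(n)) {
      nCh <- as.integer(.drawSpec(preset$channelsPerCluster, 1))
      if (nCh < 1L) next
      # uniform in disk
      rr <- preset$clusterRadius * sqrt(runif(nCh))
      th <- runif(nCh, 0, 2 * pi)
      fx <- centers$x[cl] + rr * cos(th)
      fy <- centers$y[cl] + rr * sin(th)
      nLoc <- as.integer(.drawSpec(preset$localizationsPerFluorophore, nCh))
      for (f in seq_len(nCh)) {
        m <- nLoc[f]
        if (m < 1L) next
        photons <- .drawSpec(preset$photonsPerLocalization, m)
        sigma <- preset$dlr / sqrt(photons)
        rows[[length(rows) + 1L]] <- data.frame(
          x = fx[f] + rnorm(m, 0, sigma),
          y = fy[f] + rnorm(m, 0, sigma),
          photons = photons)
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          cluster = cl, x_true = rep(fx[f], m), y_true = rep(fy[f], m))
      }
    }
    coords <- if (length(rows)) do.call(rbind, rows)
      else data.frame(x = numeric(), y = numeric(), photons = numeric())
    truth <- if (length(truthRows)) do.call(rbind, truthRows)
      else data.frame(cluster = integer(), x_true = numeric(),
                      y_true = numeric())
    coords$frame <- seq_len(nrow(coords))
    list(locs = localizationSet(coords, dlr = preset$dlr),
         centers = centers, truth = truth)
  })
}
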