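## Coupled Markov-chain gating model: kernel, simulation, likelihood and the
## maximum-likelihood kappa estimator.

#' Occupancy transition matrix of the coupled gating model
#'
#' Builds the (N+1) x (N+1) per-frame transition matrix over the number of
#' open channels, as the kappa-weighted mixture
#' \deqn{T = (1-\kappa)\,T_{ind} + \kappa\,T_{coh}.}
#' Under the independent kernel, each of the k open channels stays open with
#' probability \eqn{1 - p_{close}} and each of the N-k closed channels opens
#' with probability \eqn{p_{open}}, so
#' \eqn{T_{ind}(k \to k') = P[\mathrm{Bin}(k, 1-p_{close}) +
#' \mathrm{Bin}(N-k, p_{open}) = k']}.  The coherent kernel treats the site
#' as one super-channel: from k = 0 the site jumps to N with probability
#' \eqn{p_{open}} (else stays at 0); from any k >= 1 it closes to 0 with
#' probability \eqn{p_{close}} (else moves to N).
#'
#' @param model a [CoupledGatingModel-class].
#' @return numeric (N+1) x (N+1) row-stochastic matrix; rows and columns are
#'   labelled by occupancy 0..N.
#' @examples
#' m <- coupledGatingModel(2, pOpen = 0.5, pClose = 0.5, kappa = 0)
#' transitionMatrix(m)["1", ]   # binomial kernel: 0.25 0.50 0.25
#' @export
transitionMatrix <- function(model) {
  stopifnot(is(model, "CoupledGatingModel"))
  validObject(model)
  N <- model@nChannels
  po <- model@pOpen
  pc <- model@pClose
  kap <- model@kappa

  states <- 0:N
  Tind <- matrix(0, N + 1L, N + 1L, dimnames = list(states, states))
  for (k in states) {
    # distribution of (survivors among k open) + (openers among N-k closed)
    pStay <- stats::dbinom(0:k, k, 1 - pc)
    pOpeners <- stats::dbinom(0:(N - k), N - k, po)
    conv <- rep(0, N + 1L)
    for (s in 0:k) {
      idx <- s + 0:(N - k)
      conv[idx + 1L] <- conv[idx + 1L] + pStay[s + 1L] * pOpeners
    }
    Tind[k + 1L, ] <- conv
  }

  Tcoh <- matrix(0, N + 1L, N + 1L, dimnames = list(states, states))
  Tcoh[1L, 1L] <- 1 - po
  Tcoh[1L, N + 1L] <- po
  if (N >= 1L) for (k in 1:N) {
    Tcoh[k + 1L, 1L] <- pc
    Tcoh[k + 1L, N + 1L] <- Tcoh[k + 1L, N + 1L] + (1 - pc)
  }

  (1 - kap) * Tind + kap * Tcoh
}

#' Stationary distribution of a gating model
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' a probability vector.
#'
#' @param model a [CoupledGatingModel-class] or a stochastic matrix.
#' @return numeric probability vector over occupancy 0..N.
#' @export
stationaryDistribution <- function(model) {
  P <- if (is(model, "CoupledGatingModel")) transitionMatrix(model) else model
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("stationary distribution not found")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Simulate an occupancy trajectory
#'
#' Samples the hidden occupancy chain of the coupled gating model.
#'
#' @param model a [CoupledGatingModel-class].
#' @param nFrames number of frames (>= 1).
#' @param seed integer seed; the simulation is bit-reproducible given
#'   (model, nFrames, seed, init).
#' @param dt frame interval in seconds (default 0.01, i.e. 100 Hz imaging).
#' @param init initial occupancy in 0..N, or "stationary" to draw the first
#'   frame from the stationary distribution.
#' @return an [OccupancyTrace-class].
#' @export
simulateOccupancy <- function(model, nFrames, seed, dt = 0.01,
                              init = "stationary") {
  stopifnot(is(model, "CoupledGatingModel"), nFrames >= 1)
  P <- transitionMatrix(model)
  N <- model@nChannels
  withSeed(seed, {
    if (identical(init, "stationary")) {
      pi0 <- stationaryDistribution(model)
      k0 <- sample.int(N + 1L, 1L, prob = pi0) - 1L
    } else {
      k0 <- as.integer(init)
      if (is.na(k0) || k0 < 0L || k0 > N)
        stop("init must be an occupancy in [0, ", N, "] or \"stationary\"")
    }
    k <- .cg_simulate_chain(P, k0, as.integer(nFrames))
  })
  occupancyTrace(k, N, dt)
}

#' Quantize a calcium trace to occupancy levels
#'
#' Maps each sample to the nearest quantal level:
#' \code{k_t = clamp(round((x_t - baseline)/q), 0, nChannels)} with
#' half-quanta rounding away from zero (1.5 q maps to level 2).
#'
#' @param trace a [CalciumTrace-class] (or any [SignalTrace-class]).
#' @param q quantal amplitude per open channel (same units as the trace;
#'   nonzero).
#' @param baseline resting signal level.
#' @param nChannels maximum level N.
#' @return an [OccupancyTrace-class].
#' @export
quantizeTrace <- function(trace, q, baseline, nChannels) {
  stopifnot(is(trace, "SignalTrace"), q != 0)
  z <- (trace@values - baseline) / q
  # round half away from zero
  k <- sign(z) * floor(abs(z) + 0.5)
  k <- pmin(pmax(k, 0), nChannels)
  occupancyTrace(as.integer(k), nChannels, trace@dt)
}

## Emission means for occupancy states 0..N
.emissionMeans <- function(nChannels, q, baseline) baseline + (0:nChannels) * q

#' Log-likelihood of a trace under a coupled gating model
#'
#' Hidden-Markov forward recursion over the N+1 occupancy states with
#' Gaussian emission density (mean \code{baseline + k q}, SD
#' \code{noiseSd}); the recursion is rescaled per frame so long records stay
#' numerically finite.  The chain is initialized from its stationary
#' distribution.
#'
#' @param model a [CoupledGatingModel-class].
#' @param trace a [SignalTrace-class] with finite values.
#' @param q quantal amplitude per open channel.
#' @param baseline resting level.
#' @param noiseSd Gaussian emission SD (> 0).
#' @return log-likelihood (scalar).
#' @export
traceLogLikelihood <- function(model, trace, q, baseline, noiseSd) {
  stopifnot(is(model, "CoupledGatingModel"), is(trace, "SignalTrace"),
            noiseSd > 0)
  x <- trace@values
  if (anyNA(x) || any(!is.finite(x))) stop("trace contains non-finite values")
  P <- transitionMatrix(model)
  pi0 <- stationaryDistribution(model)
  mu <- .emissionMeans(model@nChannels, q, baseline)
  .cg_forward_loglik(x, P, pi0, mu, noiseSd)
}

#' Log-likelihood of an observed occupancy path
#'
#' Exact-state version of [traceLogLikelihood()]: the emission layer is
#' replaced by direct observation of the occupancy, so the likelihood is the
#' product of transition probabilities along the path (times the stationary
#' probability of the first state).
#'
#' @param model a [CoupledGatingModel-class].
#' @param occ an [OccupancyTrace-class] with matching nChannels.
#' @return log-likelihood (scalar).
#' @export
occupancyLogLikelihood <- function(model, occ) {
  stopifnot(is(model, "CoupledGatingModel"), is(occ, "OccupancyTrace"),
            model@nChannels == occ@nChannels)
  P <- transitionMatrix(model)
  pi0 <- stationaryDistribution(model)
  .cg_path_loglik(occ@k, P, pi0)
}

## Objective shared by both input paths
.kappaObjective <- function(trace, nChannels, q, baseline, noiseSd) {
  if (is(trace, "OccupancyTrace")) {
    function(po, pc, kap) {
      m <- coupledGatingModel(nChannels, po, pc, kap)
      occupancyLogLikelihood(m, trace)
    }
  } else {
    x <- trace@values
    mu <- .emissionMeans(nChannels, q, baseline)
    function(po, pc, kap) {
      m <- coupledGatingModel(nChannels, po, pc, kap)
      P <- transitionMatrix(m)
      pi0 <- stationaryDistribution(m)
      .cg_forward_loglik(x, P, pi0, mu, noiseSd)
    }
  }
}

#' Estimate the coupling coefficient of one record
#'
#' Maximizes the coupled-Markov-chain likelihood over
#' (pOpen, pClose, kappa).  The search is deterministic: a coarse grid
#' (kappa in steps of 0.05; probabilities log-spaced) followed by bounded
#' Nelder-Mead refinement started from the best three grid points; grid ties
#' are broken toward smaller kappa.  Probabilities are constrained to
#' [1e-4, 0.9999].  A site is classified coupled when the estimate exceeds
#' \code{threshold} (default 0.1).
#'
#' Input may be a raw fluorescence/current trace (hidden-Markov likelihood
#' with Gaussian emissions) or an already-quantized [OccupancyTrace-class]
#' (exact transition-count likelihood); both paths share the same kernel.
#'
#' @param trace a [CalciumTrace-class]/[SignalTrace-class] or an
#'   [OccupancyTrace-class].
#' @param nChannels number of channels N at the site (from the observed
#'   quantal level count; not estimated).
#' @param q quantal amplitude per open channel (default 38 nM, the analysis
#'   constant for sparklet records). Ignored for occupancy input.
#' @param baseline resting level (default 0). Ignored for occupancy input.
#' @param noiseSd emission SD; required for trace input.
#' @param threshold coupled/uncoupled cutoff on kappa (default 0.1).
#' @return a [CouplingFit-class].
#' @examples
#' m <- coupledGatingModel(2, 0.03, 0.3, kappa = 1)
#' occ <- simulateOccupancy(m, 2000, seed = 1)
#' estimateKappa(occ, nChannels = 2)
#' @export
estimateKappa <- function(trace, nChannels, q = 38, baseline = 0,
                          noiseSd = NULL, threshold = 0.1) {
  isOcc <- is(trace, "OccupancyTrace")
  len <- if (isOcc) length(trace@k) else length(trace@values)
  if (len < 100L)
    warning("trace shorter than 100 frames; kappa estimate will be noisy")
  if (!isOcc && (is.null(noiseSd) || noiseSd <= 0))
    stop("noiseSd must be supplied (and positive) for trace input")

  # degenerate record: no transitions to learn from
  vals <- if (isOcc) trace@k else trace@values
  if (length(unique(vals)) == 1L) {
    return(new("CouplingFit", kappaHat = 0, pOpenHat = .PROB_MIN,
               pCloseHat = .PROB_MIN, logLik = NA_real_, coupled = FALSE,
               nChannels = as.integer(nChannels), threshold = threshold,
               flags = "no transitions"))
  }

  obj <- .kappaObjective(trace, nChannels, q, baseline, noiseSd)

  kapGrid <- seq(0, 1, by = 0.05)
  pGrid <- 10 ^ seq(log10(2e-3), log10(0.7), length.out = 8)
  grid <- expand.grid(po = pGrid, pc = pGrid, kap = kapGrid)
  ll <- mapply(obj, grid$po, grid$pc, grid$kap)
  # ties toward smaller kappa: order by kappa then stable rank of -ll
  ord <- order(-ll, grid$kap)
  starts <- grid[ord[seq_len(3L)], , drop = FALSE]

  # refine on transformed scale: logit for probabilities, identity for kappa
  logit <- function(p) log(p / (1 - p))
  inv <- function(y) 1 / (1 + exp(-y))
  clampP <- function(p) pmin(pmax(p, .PROB_MIN), .PROB_MAX)
  neg <- function(par) {
    po <- clampP(inv(par[1])); pc <- clampP(inv(par[2]))
    kap <- min(max(par[3], 0), 1)
    -obj(po, pc, kap)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(logit(starts$po[i]), logit(starts$pc[i]), starts$kap[i])
    fit <- tryCatch(
      optim(p0, neg, method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 &&
         min(max(fit$par[3], 0), 1) < min(max(best$par[3], 0), 1)))
      best <- fit
  }
  if (is.null(best)) stop("kappa optimization failed from all starts")

  poHat <- clampP(inv(best$par[1]))
  pcHat <- clampP(inv(best$par[2]))
  kapHat <- min(max(best$par[3], 0), 1)
  flags <- character()
  new("CouplingFit", kappaHat = kapHat, pOpenHat = poHat, pCloseHat = pcHat,
      logLik = -best$value, coupled = kapHat > threshold,
      nChannels = as.integer(nChannels), threshold = threshold,
      flags = flags)
}
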