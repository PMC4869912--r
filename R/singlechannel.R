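## Quantal analysis of single-channel records: all-points histograms, the
## multi-Gaussian quantal fit, half-amplitude idealization, ensemble
## averages and NPo arithmetic.

#' All-points amplitude histogram
#'
#' Pools every sample of every sweep into bins of fixed width, aligned so
#' that one bin center sits exactly at 0 pA.
#'
#' @param sweeps a [SweepSet-class] (or numeric matrix/vector of samples).
#' @param binWidth bin width in pA (> 0); default 0.02 pA resolves the
#'   ~0.5 pA quantal spacing of Ca2+ unitary currents.
#' @return an [AllPointsHistogram-class].
#' @export
allPointsHistogram <- function(sweeps, binWidth = 0.02) {
  stopifnot(binWidth > 0)
  x <- if (is(sweeps, "SweepSet")) as.vector(sweeps@sweeps)
       else as.vector(sweeps)
  if (!length(x)) stop("empty sweep set")
  idx <- as.integer(round(x / binWidth))
  lo <- min(idx); hi <- max(idx)
  counts <- tabulate(idx - lo + 1L, nbins = hi - lo + 1L)
  new("AllPointsHistogram", binCenters = (lo:hi) * binWidth,
      counts = as.integer(counts), binWidth = binWidth)
}

## Sum-of-quantal-Gaussians model: component j has mean j*q, variance j*b.
.quantalCurve <- function(centers, q, b, a) {
  y <- 0
  for (j in seq_along(a))
    y <- y + a[j] * exp(-(centers - j * q) ^ 2 / (2 * j * b))
  y
}

#' Fit the quantal multi-Gaussian model to a histogram
#'
#' Nonlinear least squares of
#' \deqn{N(i) = \sum_{j=1}^{n} a_j \exp[-(i - jq)^2 / (2jb)]}
#' to histogram counts: each open level j is a Gaussian with mean
#' \eqn{jq} and variance \eqn{jb} (level-proportional broadening), sharing
#' the single quantal unit q.  The closed (j = 0) peak is not part of the
#' sum; when \code{fitBaseline = TRUE} a separate Gaussian is fitted near
#' zero and subtracted before the quantal fit.
#'
#' Optimization uses three starts with q seeded at \code{qInit} times
#' (0.5, 1, 2); component amplitudes are constrained nonnegative.  With
#' \code{qInit = "auto"} the seed is the location of the largest
#' non-zero-centered histogram peak.
#'
#' @param hist an [AllPointsHistogram-class].
#' @param nComponents number of open-level components (>= 1).
#' @param qInit initial quantal unit (signed, pA) or "auto".
#' @param fitBaseline fit-and-subtract the closed peak first (default TRUE).
#' @return a [QuantalFit-class]; \code{quantalUnit()} returns the signed q.
#' @export
fitQuantalGaussians <- function(hist, nComponents = 2, qInit = "auto",
                                fitBaseline = TRUE) {
  stopifnot(is(hist, "AllPointsHistogram"), nComponents >= 1)
  centers <- hist@binCenters
  counts <- as.numeric(hist@counts)
  if (sum(counts > 0) < 5 * nComponents)
    stop("too few occupied bins for ", nComponents, " components")

  if (identical(qInit, "auto")) {
    # smooth lightly, list local maxima, take the largest away from zero
    sm <- as.numeric(stats::filter(counts, rep(1 / 5, 5), sides = 2))
    sm[is.na(sm)] <- counts[is.na(sm)]
    n <- length(sm)
    isMax <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                       sm[2:(n - 1)] >= sm[3:n], FALSE)
    zeroPk <- which.min(abs(centers))  # the closed peak sits near 0
    cand <- which(isMax & abs(centers - centers[zeroPk]) >
                    3 * hist@binWidth)
    if (!length(cand)) stop("no off-zero peak found for qInit")
    qInit <- centers[cand[which.max(sm[cand])]]
  }
  if (qInit == 0) stop("qInit must be nonzero")

  ## The quantal sum starts at j = 1; the closed (j = 0) peak is a separate
  ## free Gaussian (a0, mu0, sd0).  Both are estimated in one joint least
  ## squares so neither peak's tail biases the other, and only the quantal
  ## parameters are reported as the fit.
  seedA <- function(q) vapply(seq_len(nComponents), function(j) {
    i <- which.min(abs(centers - j * q))
    sqrt(max(counts[i], 1))
  }, numeric(1))
  nq <- 2L + nComponents  # q, log b, sqrt a_j
  obj <- function(p) {
    q <- p[1]; b <- exp(p[2]); a <- p[3:nq] ^ 2
    mdl <- .quantalCurve(centers, q, b, a)
    if (fitBaseline) {
      a0 <- p[nq + 1L] ^ 2; mu0 <- p[nq + 2L]; sd0 <- exp(p[nq + 3L])
      mdl <- mdl + a0 * exp(-(centers - mu0) ^ 2 / (2 * sd0 ^ 2))
    }
    sum((counts - mdl) ^ 2)
  }
  sd0i <- max(abs(qInit) / 6, hist@binWidth)
  best <- NULL
  for (mult in c(1, 0.5, 2)) {
    q0 <- qInit * mult
    p0 <- c(q0, log(sd0i ^ 2), seedA(q0))
    if (fitBaseline) {
      i0 <- which.min(abs(centers))
      p0 <- c(p0, sqrt(max(counts[i0], 1)), 0, log(sd0i))
    }
    fit <- tryCatch({
      f <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-14))
      # fresh simplex from the optimum guards against premature collapse
      optim(f$par, obj, method = "Nelder-Mead",
            control = list(maxit = 20000, reltol = 1e-14))
    }, error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("quantal fit did not converge from any start")
  base <- c(a0 = NA_real_, mu0 = NA_real_, sd0 = NA_real_)
  if (fitBaseline)
    base <- c(a0 = best$par[nq + 1L] ^ 2, mu0 = best$par[nq + 2L],
              sd0 = exp(best$par[nq + 3L]))
  tot <- sum(counts ^ 2)
  if (tot > 0 && best$value > 0.9 * tot)
    stop("quantal fit did not converge; best residual ", signif(best$value, 4))

  new("QuantalFit", q = best$par[1], b = exp(best$par[2]),
      a = best$par[3:nq] ^ 2, nComponents = as.integer(nComponents),
      residual = best$value, baselinePeak = unname(base))
}

#' Idealize sweeps to occupancy levels
#'
#' Half-amplitude threshold idealization:
#' \code{k_t = clamp(round(x_t / q), 0, kMax)}.  An optional width-3 median
#' prefilter suppresses single-sample noise spikes.
#'
#' @param sweeps a [SweepSet-class].
#' @param q unitary current (signed, nonzero pA).
#' @param kMax maximum level; default the largest level seen in the data.
#' @param medianFilter apply a running-median prefilter first.
#' @param medianWidth odd median window width (default 3; 5 suppresses
#'   more noise at the cost of blurring sub-window events).
#' @return list of [OccupancyTrace-class], one per sweep.
#' @export
idealizeSweeps <- function(sweeps, q, kMax = NULL, medianFilter = FALSE,
                           medianWidth = 3) {
  stopifnot(is(sweeps, "SweepSet"), q != 0)
  lapply(seq_len(ncol(sweeps@sweeps)), function(s) {
    x <- sweeps@sweeps[, s]
    if (medianFilter && length(x) >= medianWidth)
      x <- stats::runmed(x, medianWidth, endrule = "keep")
    k <- round(x / q)
    k[k < 0] <- 0
    km <- if (is.null(kMax)) max(1, max(k)) else kMax
    k <- pmin(k, km)
    occupancyTrace(as.integer(k), nChannels = km, dt = sweeps@dt)
  })
}

#' Ensemble average of sweeps
#'
#' @param sweeps a [SweepSet-class].
#' @return a [CurrentTrace-class]: the pointwise mean across sweeps.
#' @export
ensembleAverage <- function(sweeps) {
  stopifnot(is(sweeps, "SweepSet"))
  currentTrace(rowMeans(sweeps@sweeps), sweeps@dt)
}

#' NPo from macroscopic and unitary current
#'
#' The whole-cell current obeys I = i N Po, so the activity NPo is
#' \code{|I| / |i|}.
#'
#' @param iMacroscopic whole-cell current (pA).
#' @param iUnitary unitary current (pA, nonzero, same sign convention).
#' @return list(npo, iUnitary, iMacroscopic).
#' @examples
#' estimateNpo(-480, -0.16)$npo   # 3000
#' @export
estimateNpo <- function(iMacroscopic, iUnitary) {
  if (iUnitary == 0) stop("unitary current must be nonzero")
  if (iMacroscopic != 0 && sign(iMacroscopic) != sign(iUnitary))
    warning("macroscopic and unitary currents have opposite signs")
  list(npo = abs(iMacroscopic) / abs(iUnitary),
       iUnitary = iUnitary, iMacroscopic = iMacroscopic)
}

#' Ca2+/Ba2+ fold change in NPo
#'
#' Ratio of channel activity with Ca2+ versus Ba2+ as charge carrier:
#' \code{(|I_Ca|/|i_Ca|) / (|I_Ba|/|i_Ba|)}.  Default unitary currents are
#' the 2 mM values at -10 mV: -0.16 pA (Ca2+) and -0.24 pA (Ba2+).
#'
#' @param iCaMacro,iBaMacro whole-cell currents (pA).
#' @param iUnitCa,iUnitBa unitary currents (pA).
#' @return dimensionless fold change; equal macroscopic currents give
#'   0.24/0.16 = 1.5.
#' @export
foldChangeNpo <- function(iCaMacro, iBaMacro, iUnitCa = -0.16,
                          iUnitBa = -0.24) {
  estimateNpo(iCaMacro, iUnitCa)$npo / estimateNpo(iBaMacro, iUnitBa)$npo
}
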