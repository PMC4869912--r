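## Macroscopic-current metrics: conductance transform, Boltzmann fit,
## Ca2+-dependent inactivation (r300/f300), activation tau, and the split
## fluorophore F/F0-voltage relation.

#' Conductance-voltage curve from an I-V table
#'
#' Converts currents to chord conductances, \code{G = I / (V - eRev)}, and
#' normalizes to the maximum so the largest conductance is 1.  Points at the
#' reversal potential have zero driving force and are excluded with a
#' warning.
#'
#' @param iv data.frame (or 2-column matrix) with columns v (mV) and i (pA).
#' @param eRev reversal potential (mV).
#' @return data.frame with columns v and g_norm (max 1).
#' @export
conductanceCurve <- function(iv, eRev) {
  iv <- as.data.frame(iv)
  names(iv)[1:2] <- c("v", "i")
  atRev <- iv$v == eRev
  if (any(atRev)) {
    warning(sum(atRev), " point(s) at the reversal potential excluded")
    iv <- iv[!atRev, , drop = FALSE]
  }
  if (!nrow(iv)) stop("no usable I-V points")
  g <- iv$i / (iv$v - eRev)
  gmax <- max(g)
  if (gmax <= 0) stop("all conductances nonpositive; check sign conventions")
  data.frame(v = iv$v, g_norm = g / gmax)
}

#' Fit a Boltzmann activation function
#'
#' Least-squares fit of \eqn{g(V) = 1/(1 + \exp((V_{1/2} - V)/k))} to a
#' normalized conductance curve.  Initialization: vHalf at the voltage whose
#' g is closest to 0.5, slope 8 mV.
#'
#' @param gv data.frame with columns v and g_norm (from
#'   [conductanceCurve()]); needs >= 4 points spanning the transition.
#' @return a [BoltzmannFit-class].
#' @export
fitBoltzmann <- function(gv) {
  gv <- as.data.frame(gv)
  names(gv)[1:2] <- c("v", "g_norm")
  if (nrow(gv) < 4) stop("need at least 4 points for a Boltzmann fit")
  if (diff(range(gv$g_norm)) < 0.2)
    stop("conductance curve does not span the transition (saturated data)")
  vh0 <- gv$v[which.min(abs(gv$g_norm - 0.5))]
  obj <- function(p) {
    k <- exp(p[2])
    sum((gv$g_norm - 1 / (1 + exp((p[1] - gv$v) / k))) ^ 2)
  }
  fit <- optim(c(vh0, log(8)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 0.5 * sum((gv$g_norm - mean(gv$g_norm)) ^ 2))
    stop("Boltzmann fit did not converge; residual ", signif(fit$value, 4))
  new("BoltzmannFit", vHalf = fit$par[1], slopeK = exp(fit$par[2]),
      residual = fit$value)
}

## 5-sample moving mean (peaks are read off the smoothed trace so single
## noise spikes do not masquerade as the peak)
.smooth5 <- function(x) {
  if (length(x) < 5) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2))
  y[is.na(y)] <- x[is.na(y)]
  y
}

#' Calcium-dependent inactivation metrics
#'
#' Computes, per trace, the fraction of peak current remaining at
#' \code{tEval} ms (r300 for the default 300 ms) using absolute currents,
#' then \code{f300 = r300(Ba) - r300(Ca)} — positive when Ca2+ inactivates
#' the current more strongly than Ba2+ — and percent inactivation
#' \code{100 (1 - r)} of the Ca2+ trace at 25 ms and at \code{tEval}.
#'
#' @param traceCa,traceBa [CurrentTrace-class] objects starting at the
#'   depolarization onset (t = 0).
#' @param tEval evaluation time in ms (default 300).
#' @return list with r300_ca, r300_ba, f300, pct_inact_25, pct_inact_300.
#' @export
cdiMetrics <- function(traceCa, traceBa, tEval = 300) {
  frac <- function(tr, tms) {
    x <- .smooth5(abs(tr@values))
    dtms <- tr@dt * 1000
    idx <- round(tms / dtms) + 1L
    if (idx > length(x)) stop("trace shorter than ", tms, " ms")
    pk <- max(x)
    if (pk == 0) stop("zero peak current")
    x[idx] / pk
  }
  rCa <- frac(traceCa, tEval)
  rBa <- frac(traceBa, tEval)
  list(r300_ca = rCa, r300_ba = rBa, f300 = rBa - rCa,
       pct_inact_25 = 100 * (1 - frac(traceCa, 25)),
       pct_inact_300 = 100 * (1 - rCa))
}

#' Activation time constant by single-exponential fit
#'
#' Fits \eqn{I(t) = I_{max} (1 - e^{-t/\tau})} to the activation phase,
#' from the depolarization onset to the (smoothed) current peak.
#'
#' @param trace a [CurrentTrace-class] starting at the onset.
#' @return tau in ms.
#' @export
fitActivationTau <- function(trace) {
  x <- trace@values
  ax <- .smooth5(abs(x))
  pk <- which.max(ax)
  if (pk <= 2) stop("no activation phase: trace peaks at onset")
  tms <- (seq_along(x) - 1) * trace@dt * 1000
  tt <- tms[1:pk]
  yy <- abs(x)[1:pk]
  ymax <- max(yy)
  obj <- function(p) {
    tau <- exp(p[2])
    sum((yy - p[1] * (1 - exp(-tt / tau))) ^ 2)
  }
  fit <- optim(c(ymax, log(max(tt[pk] / 3, 1e-3))), obj,
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
  exp(fit$par[2])
}

#' Fluorescence-voltage relation (split-fluorophore reconstitution)
#'
#' For each voltage's image stack, averages the last 10 frames, sums the
#' average over the cell mask, and divides by the value at the baseline
#' (holding) voltage, so F/F0 at -80 mV is 1 by construction.
#'
#' @param stacks named or unnamed list of [ImageStack-class], one per
#'   voltage.
#' @param voltages numeric vector of test potentials (mV), same length.
#' @param baselineVoltage holding potential whose stack defines F0
#'   (default -80 mV).
#' @param mask optional logical matrix selecting cell pixels (default all).
#' @return data.frame with columns v and f_over_f0, sorted by voltage.
#' @export
fluorescenceVoltageRelation <- function(stacks, voltages,
                                        baselineVoltage = -80,
                                        mask = NULL) {
  stopifnot(length(stacks) == length(voltages))
  if (!any(voltages == baselineVoltage))
    stop("missing stack at the baseline voltage ", baselineVoltage, " mV")
  totals <- vapply(stacks, function(st) {
    d <- st@data
    nf <- dim(d)[3]
    if (nf < 10) stop("stacks need at least 10 frames")
    avg <- apply(d[, , (nf - 9):nf, drop = FALSE], c(1, 2), mean)
    if (!is.null(mask)) sum(avg[mask]) else sum(avg)
  }, numeric(1))
  f0 <- totals[voltages == baselineVoltage][1]
  if (f0 == 0) stop("baseline fluorescence is zero")
  out <- data.frame(v = voltages, f_over_f0 = totals / f0)
  out[order(out$v), , drop = FALSE]
}
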