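## Shared fixtures, built in code.

# noiseless bleaching staircase: nSteps drops of `step` at `frames`
makeStaircase <- function(nFrames, frames, step = 100, top = NULL,
                          offset = 50) {
  if (is.null(top)) top <- length(frames) * step
  x <- rep(top, nFrames)
  for (b in frames) x[(b + 1):nFrames] <- x[(b + 1):nFrames] - step
  x + offset
}

# brute-force HMM likelihood by exhaustive path enumeration (oracle)
bruteForceLogLik <- function(model, x, q, baseline, noiseSd) {
  P <- transitionMatrix(model)
  pi0 <- stationaryDistribution(model)
  N <- nChannels(model)
  paths <- expand.grid(rep(list(0:N), length(x)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    k <- as.integer(paths[r, ])
    p <- pi0[k[1] + 1]
    if (length(x) > 1)
      for (t in 2:length(x)) p <- p * P[k[t - 1] + 1, k[t] + 1]
    tot <- tot + p * prod(dnorm(x, baseline + q * k, noiseSd))
  }
  log(tot)
}

# hand enumeration of the independent two-channel kernel (oracle for N = 2)
independentKernel2 <- function(pOpen, pClose) {
  single <- matrix(c(1 - pOpen, pOpen, pClose, 1 - pClose), 2, 2,
                   byrow = TRUE)
  out <- matrix(0, 3, 3, dimnames = list(0:2, 0:2))
  for (a in 0:1) for (b in 0:1) for (a2 in 0:1) for (b2 in 0:1) {
    out[a + b + 1, a2 + b2 + 1] <- out[a + b + 1, a2 + b2 + 1] +
      single[a + 1, a2 + 1] * single[b + 1, b2 + 1] / ifelse(a + b == 1, 2, 1)
  }
  # rows for occupancy 1 were accumulated over both orderings (1,0) and
  # (0,1); each contributes with weight 1/2 (exchangeable channels)
  out
}
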