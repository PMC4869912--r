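test_that("sparklet generator obeys its stated signal model", {
  gp <- gatingPreset("cav13s_sparklet")
  sp <- signalPreset("sparklet_default")

  # same seed twice: bit-identical trace and occupancy
  a <- makeSparkletTrace(gp, sp, 1000, seed = 7)
  b <- makeSparkletTrace(gp, sp, 1000, seed = 7)
  expect_identical(traceValues(a$trace), traceValues(b$trace))
  expect_identical(occupancy(a$occupancy), occupancy(b$occupancy))

  # occupancy-conditioned means sit at baseline + {0, 38, 76} nM
  sim <- makeSparkletTrace(gp, sp, 20000, seed = 8)
  x <- traceValues(sim$trace)
  k <- occupancy(sim$occupancy)
  for (lev in 0:2) {
    n <- sum(k == lev)
    if (n > 10)
      expect_lt(abs(mean(x[k == lev]) - (100 + 38 * lev)),
                3 * sp$noiseSd / sqrt(n))
  }

  # noise is additive and unbiased
  expect_lt(abs(mean(x - 38 * k - 100)), 3 * sp$noiseSd / sqrt(length(x)))

  # no openings possible: constant trace at baseline
  quiet <- makeSparkletTrace(coupledGatingModel(2, 1e-12, 0.5, 0),
                             signalPreset("sparklet_default", noiseSd = 0),
                             100, seed = 1)
  expect_true(all(traceValues(quiet$trace) == 100))
})

test_that("invalid generator configuration names the offending field", {
  expect_error(signalPreset(quantalAmplitude = 0, baseline = 0,
                            noiseSd = 1, dt = 0.01), "quantalAmplitude")
  expect_error(signalPreset(quantalAmplitude = 38, baseline = 0,
                            noiseSd = -1, dt = 0.01), "noiseSd")
  expect_error(signalPreset(quantalAmplitude = 38, baseline = 0,
                            noiseSd = 1, dt = 0), "dt")
  expect_error(gatingPreset("nonexistent"), "unknown gating preset")
})

test_that("single-channel sweeps carry the preset unitary current", {
  gp <- gatingPreset("single_channel_bayk")
  # open level minus closed level equals the quantal current exactly when
  # noiseless
  sp0 <- signalPreset("cav13s_ca_m30", noiseSd = 0)
  sim <- makeSingleChannelSweeps(gp, sp0, 10, 20000, seed = 12)
  x <- as.vector(sim$sweeps@sweeps)
  k <- unlist(lapply(sim$occupancy, occupancy))
  expect_equal(mean(x[k == 1]) - mean(x[k == 0]), -0.49)

  # ground-truth occupancy matches the chain's stationary distribution.
  # Dwells last hundreds of frames, so the effective sample size is the
  # number of gating cycles, not the frame count.
  pi0 <- stationaryDistribution(gp)
  probs <- gatingProbabilities(gp)
  nCycles <- length(k) / (1 / probs["pOpen"] + 1 / probs["pClose"])
  expect_lt(abs(mean(k) - pi0[2]),
            3 * sqrt(pi0[2] * (1 - pi0[2]) / nCycles))

  # always-open, noiseless: every frame at baseline + iUnitary
  alwaysOpen <- coupledGatingModel(1, 0.9999, 1e-4, 0)
  sim2 <- makeSingleChannelSweeps(alwaysOpen, sp0, 1, 100, seed = 1)
  expect_true(all(abs(sim2$sweeps@sweeps - (-0.49)) < 1e-12 |
                    sim2$sweeps@sweeps == 0))
  expect_error(makeSingleChannelSweeps(gp, sp0, 1, 1, seed = 1),
               "sweepFrames")
})

test_that("whole-cell trace follows the two-exponential kinetic model", {
  # v = eRev gives a zero deterministic trace
  z <- makeWholeCellTrace(10, v = 54, eRev = 54, duration = 50, dt = 0.1)
  expect_true(all(traceValues(z) == 0))

  # negligible inactivation: late current approaches gMax * (v - eRev)
  tr <- makeWholeCellTrace(10, v = -10, eRev = 54, tauAct = 1,
                           tauInact = 1e9, duration = 100, dt = 0.05)
  expect_equal(tail(traceValues(tr), 1), 10 * (-10 - 54), tolerance = 1e-6)

  expect_error(makeWholeCellTrace(10, -10, tauAct = -1), "tauAct")
})

test_that("bleach stacks encode the planted staircases", {
  # forced bleach frames give a deterministic 3-step z-profile
  bp <- bleachPreset(forcedBleachFrames = list(c(100, 200, 300)),
                     noiseSd = 0, nFrames = 400)
  sim <- makeBleachStack(bp, nSpots = 1, imageSize = 32, seed = 1)
  roi <- data.frame(row0 = sim$spots$row[1] - 1, col0 = sim$spots$col[1] - 1)
  z <- traceValues(extractTrace(sim$stack, roi))
  lv <- c(mean(z[1:100]), mean(z[101:200]), mean(z[201:300]),
          mean(z[301:400]))
  expect_true(all(diff(lv) < 0))
  expect_equal(length(unique(round(diff(lv), 6))), 1)  # equal step sizes

  # single fluorophore, no noise: exactly one downward step to background
  bp1 <- bleachPreset(nFluorophores = 1, noiseSd = 0, nFrames = 200,
                      bleachRate = 0.02)
  sim1 <- makeBleachStack(bp1, 1, 32, seed = 4)
  z1 <- traceValues(extractTrace(
    sim1$stack, data.frame(row0 = sim1$spots$row[1] - 1,
                           col0 = sim1$spots$col[1] - 1)))
  expect_equal(length(unique(round(z1, 9))), 2)

  # requested mixture proportions are reproduced (chi-square at n = 500)
  mix <- distributionSpec("categorical", values = c(1, 3, 5),
                          probs = c(0.2, 0.3, 0.5))
  bp2 <- bleachPreset(nFluorophores = mix, nFrames = 10)
  sim2 <- makeBleachStack(bp2, 500, imageSize = 256, seed = 10)
  tab <- table(factor(sim2$spots$nFluorophores, levels = c(1, 3, 5)))
  pval <- suppressWarnings(
    chisq.test(as.vector(tab), p = c(0.2, 0.3, 0.5))$p.value)
  expect_gt(pval, 0.001)

  expect_error(makeBleachStack(bp1, nSpots = 1000, imageSize = 32, seed = 1),
               "too many spots")
})

test_that("localization scatter follows the photon-budget precision law", {
  pre <- emitterCloudPreset(
    nClusters = 1, channelsPerCluster = 1, clusterRadius = 0,
    localizationsPerFluorophore = distributionSpec("fixed", value = 1e4),
    photonsPerLocalization = distributionSpec("fixed", value = 1900))
  sim <- makeLocalizations(pre, seed = 13)
  xy <- localizations(sim$locs)
  sig <- localizationPrecision(710, 1900)  # 16.3 nm
  # empirical SD within 2% at 1e4 events (pooled over both axes)
  empirical <- sqrt((var(xy$x) + var(xy$y)) / 2)
  expect_lt(abs(empirical - sig) / sig, 0.02)

  # photons -> infinity collapses localizations onto the true positions
  pre2 <- emitterCloudPreset(
    nClusters = 2, channelsPerCluster = 3, clusterRadius = 20,
    localizationsPerFluorophore = distributionSpec("fixed", value = 5),
    photonsPerLocalization = distributionSpec("fixed", value = 1e12))
  sim2 <- makeLocalizations(pre2, seed = 14)
  xy2 <- localizations(sim2$locs)
  expect_lt(max(abs(xy2$x - sim2$truth$x_true)), 0.1)

  # determinism
  sim3 <- makeLocalizations(pre2, seed = 14)
  expect_identical(localizations(sim2$locs), localizations(sim3$locs))
})

test_that("substreams decouple the generators", {
  # the occupancy stream does not depend on whether noise is drawn
  gp <- gatingPreset("cav13s_sparklet")
  spN <- signalPreset("sparklet_default")
  sp0 <- signalPreset("sparklet_default", noiseSd = 0)
  a <- makeSparkletTrace(gp, spN, 500, seed = 99)
  b <- makeSparkletTrace(gp, sp0, 500, seed = 99)
  expect_identical(occupancy(a$occupancy), occupancy(b$occupancy))
  expect_true(substreamSeed(1, "a") != substreamSeed(1, "b"))
  expect_lt(substreamSeed(123456, "some_long_stream_name"), 2^31)
})
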