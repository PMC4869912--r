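test_that("event detection finds hand-built square pulses", {
  x <- rep(100, 60)
  x[11:15] <- 100 + 38        # 1q for 5 frames
  x[31:33] <- 100 + 76        # 2q for 3 frames
  ev <- detectEvents(calciumTrace(x, 0.01), q = 38, baseline = 100)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$level, c(1L, 2L))
  expect_equal(ev$start_frame, c(11L, 31L))
  expect_equal(ev$end_frame, c(15L, 33L))
  expect_equal(ev$mean_amplitude, c(38, 76))

  # flat trace: no events
  expect_equal(nrow(detectEvents(calciumTrace(rep(100, 50), 0.01), 38, 100)),
               0)

  # single-frame excursions are rejected by the 2-frame minimum
  x1 <- rep(100, 50); x1[20] <- 150
  expect_equal(nrow(detectEvents(calciumTrace(x1, 0.01), 38, 100)), 0)

  expect_error(detectEvents(calciumTrace(rep(100, 50), 0.01), q = -1),
               "q must be positive")
})

test_that("events match ground-truth occupancy runs on noiseless traces", {
  gp <- gatingPreset("cav13s_sparklet")
  sp <- signalPreset("sparklet_default", noiseSd = 0)
  sim <- makeSparkletTrace(gp, sp, 2000, seed = 17)
  k <- occupancy(sim$occupancy)
  ev <- detectEvents(sim$trace, 38, baseline = 100, minDurationFrames = 1)
  r <- rle(k >= 1L)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  expect_equal(ev$start_frame, starts[r$values])
  expect_equal(ev$end_frame, ends[r$values])
  # event level equals the max occupancy inside each run
  expect_equal(ev$level,
               mapply(function(s, e) max(k[s:e]),
                      starts[r$values], ends[r$values]))
})

test_that("nPs is time-averaged occupancy and is consistent with events", {
  # k = 2 for half the frames: nps = 1, Ps = 0.5, 2 levels
  x <- c(rep(100 + 76, 50), rep(100, 50))
  s <- siteNps(calciumTrace(x, 0.01), 38, baseline = 100)
  expect_equal(s@nps, 1.0)
  expect_equal(s@activeFraction, 0.5)
  expect_equal(s@nLevels, 2L)

  # all-closed: nps 0, no events
  s0 <- siteNps(calciumTrace(rep(100, 50), 0.01), 38, 100)
  expect_equal(s0@nps, 0)
  expect_equal(nrow(sparkletEvents(s0)), 0)

  # event-based and frame-based nPs agree on noiseless traces
  sim <- makeSparkletTrace(gatingPreset("cav13s_sparklet"),
                           signalPreset("sparklet_default", noiseSd = 0),
                           2000, seed = 18)
  st <- siteNps(sim$trace, 38, 100, minDurationFrames = 1)
  expect_equal(st@nps, mean(occupancy(sim$occupancy)))
})

test_that("depolarization preset raises nPs roughly three-fold", {
  npsOf <- function(preset, seeds) {
    mean(vapply(seeds, function(i) {
      sim <- makeSparkletTrace(gatingPreset(preset),
                               signalPreset("sparklet_default"),
                               2000, seed = 2000 + i)
      siteNps(sim$trace, 38, baseline = 100)@nps
    }, numeric(1)))
  }
  rest <- npsOf("cav13s_sparklet", 1:8)
  depol <- npsOf("cav13s_sparklet_depol", 1:8)
  # opening rate tripled at fixed closing rate: ~3x occupancy
  expect_gt(depol / rest, 2)
  expect_lt(depol / rest, 4.5)
})

test_that("amplitude fit returns the elementary sparklet amplitude", {
  # events tightly spread around multiples of 38 recover q = 38 (a small
  # spread is needed to satisfy the occupied-bins precondition)
  set.seed(90)
  amps <- rep(c(38, 76), c(60, 25)) + rnorm(85, 0, 3)
  f <- fitEventAmplitudes(amps, binWidth = 4)
  expect_equal(quantalUnit(f), 38, tolerance = 0.05)

  # doubling all amplitudes doubles q-hat
  f2 <- fitEventAmplitudes(amps * 2, binWidth = 8)
  expect_equal(quantalUnit(f2) / quantalUnit(f), 2, tolerance = 0.01)

  expect_error(fitEventAmplitudes(rep(38, 10)), "at least 30")
})

test_that("sparklet density counts active sites per area", {
  mkSite <- function(active) {
    x <- rep(100, 60)
    if (active) x[11:20] <- 138
    siteNps(calciumTrace(x, 0.01), 38, 100)
  }
  sites <- c(lapply(1:5, function(i) mkSite(TRUE)),
             lapply(1:3, function(i) mkSite(FALSE)))
  expect_equal(sparkletDensity(sites, 100), 0.05)
  expect_equal(sparkletDensity(list(), 10), 0)
  expect_error(sparkletDensity(sites, 0), "positive")

  # partitioning the footprint conserves the total count
  d1 <- sparkletDensity(sites[1:2], 40) * 40
  d2 <- sparkletDensity(sites[3:8], 60) * 60
  expect_equal(d1 + d2, sparkletDensity(sites, 100) * 100)
})

test_that("fluorescence calibration converts to nM and inverts", {
  # linear: F = Frest maps to resting [Ca2+]
  tr <- bleachTrace(c(10, 12, 14), 0.01)
  ca <- fluorescenceToCa(tr, "linear",
                         list(scale = 19, fRest = 10, caRest = 100))
  expect_equal(traceValues(ca), c(100, 138, 176))

  # linear round-trip
  back <- (traceValues(ca) - 100) / 19 + 10
  expect_equal(back, c(10, 12, 14))

  # saturating: F midway between Fmin and Fmax gives Kd
  ca2 <- fluorescenceToCa(c(55), "saturating",
                          list(kd = 320, fMin = 10, fMax = 100), dt = 0.01)
  expect_equal(traceValues(ca2), 320)
  expect_error(
    fluorescenceToCa(c(150), "saturating",
                     list(kd = 320, fMin = 10, fMax = 100), dt = 0.01),
    "fMax")
  expect_error(fluorescenceToCa(tr, "linear", list(scale = 1)),
               "incomplete")
})

test_that("kappa handoff separates coupled from independent presets", {
  kapOf <- function(preset, n) {
    vapply(seq_len(n), function(i) {
      sim <- makeSparkletTrace(gatingPreset(preset),
                               signalPreset("sparklet_default"),
                               1500, seed = 3000 + i)
      kappa(estimateKappa(sim$trace, 2, q = 38, baseline = 100, noiseSd = 8))
    }, numeric(1))
  }
  expect_lt(mean(kapOf("independent_sparklet", 6)),
            mean(kapOf("cav13s_sparklet", 6)))
})
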