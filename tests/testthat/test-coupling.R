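test_that("transition matrix matches hand-computed kernels", {
  # kappa = 0, N = 2, symmetric probabilities: binomial row from k = 1
  m <- coupledGatingModel(2, 0.5, 0.5, kappa = 0)
  P <- transitionMatrix(m)
  expect_equal(unname(P["1", ]), c(0.25, 0.5, 0.25))

  # kappa = 0 equals the independent-channels kernel enumerated by hand
  m2 <- coupledGatingModel(2, 0.2, 0.4, kappa = 0)
  expect_equal(unname(transitionMatrix(m2)),
               unname(independentKernel2(0.2, 0.4)), tolerance = 1e-12)

  # kappa = 1: from 0 mass only on {0, N} with P(0 -> N) = pOpen
  m3 <- coupledGatingModel(3, 0.1, 0.3, kappa = 1)
  P3 <- transitionMatrix(m3)
  expect_equal(unname(P3["0", ]), c(0.9, 0, 0, 0.1))
  expect_equal(unname(P3["2", ]), c(0.3, 0, 0, 0.7))

  # kappa = 0.5: every entry is the average of the two kernels
  m4 <- coupledGatingModel(2, 0.2, 0.4, kappa = 0.5)
  Tind <- independentKernel2(0.2, 0.4)
  Tcoh <- matrix(c(0.8, 0, 0.2,  0.4, 0, 0.6,  0.4, 0, 0.6), 3, 3,
                 byrow = TRUE)
  expect_equal(unname(transitionMatrix(m4)),
               unname(0.5 * Tind + 0.5 * Tcoh), tolerance = 1e-12)
})

test_that("rows of the transition matrix sum to 1 for random models", {
  set.seed(11)
  for (i in 1:1000) {
    m <- coupledGatingModel(sample(1:4, 1), runif(1, 0.01, 0.99),
                            runif(1, 0.01, 0.99), runif(1))
    expect_lt(max(abs(rowSums(transitionMatrix(m)) - 1)), 1e-12)
  }
})

test_that("stationary extreme-state mass is nondecreasing in kappa", {
  for (po in c(0.05, 0.3)) for (pc in c(0.1, 0.5)) {
    mass <- vapply(seq(0, 1, by = 0.1), function(k) {
      pi0 <- stationaryDistribution(coupledGatingModel(3, po, pc, k))
      pi0[1] + pi0[4]
    }, numeric(1))
    expect_true(all(diff(mass) >= -1e-10))
  }
})

test_that("simulated occupancy follows the stationary distribution", {
  m <- coupledGatingModel(2, 0.1, 0.3, kappa = 0.4)
  occ <- simulateOccupancy(m, 1e5, seed = 21)
  pi0 <- stationaryDistribution(m)
  freq <- tabulate(occupancy(occ) + 1L, 3) / 1e5
  # 3 sigma multinomial error per level, on the effective sample size
  # (dwell times of ~1/p frames make consecutive frames dependent)
  nEff <- 1e5 / (1 / 0.1 + 1 / 0.3)
  tol <- 3 * sqrt(pi0 * (1 - pi0) / nEff)
  expect_true(all(abs(freq - pi0) < tol))

  # determinism under a fixed seed
  occ2 <- simulateOccupancy(m, 1e5, seed = 21)
  expect_identical(occupancy(occ), occupancy(occ2))

  # pOpen ~ 0 and init 0 stays closed
  m0 <- coupledGatingModel(2, 1e-12, 0.5, 0)
  expect_true(all(occupancy(simulateOccupancy(m0, 1000, 1, init = 0)) == 0))

  # kappa = 1 visits only {0, N} after the first coherent transition
  m1 <- coupledGatingModel(3, 0.2, 0.3, kappa = 1)
  k <- occupancy(simulateOccupancy(m1, 5000, seed = 5, init = 2))
  firstMove <- which(diff(k) != 0)[1]
  expect_true(all(k[(firstMove + 1):length(k)] %in% c(0L, 3L)))
})

test_that("quantization rounds half-quanta away from zero and clamps", {
  tr <- calciumTrace(c(0, 19, 18.9, 57, 200) + 100, dt = 0.01)
  k <- occupancy(quantizeTrace(tr, q = 38, baseline = 100, nChannels = 3))
  expect_identical(k, c(0L, 1L, 0L, 2L, 3L))  # 0.5q up, clamp at N

  # noiseless generator round-trip recovers ground truth exactly
  gp <- gatingPreset("cav13s_sparklet")
  sp <- signalPreset("sparklet_default", noiseSd = 0)
  sim <- makeSparkletTrace(gp, sp, 500, seed = 3)
  expect_identical(
    occupancy(quantizeTrace(sim$trace, 38, 100, 2)),
    occupancy(sim$occupancy))
})

test_that("forward likelihood equals exhaustive path enumeration", {
  set.seed(31)
  for (rep in 1:5) {
    m <- coupledGatingModel(2, runif(1, 0.05, 0.5), runif(1, 0.05, 0.5),
                            runif(1))
    for (len in c(1, 3, 6)) {
      x <- rnorm(len, sample(c(0, 38, 76), len, TRUE), 8)
      tr <- calciumTrace(x, 0.01)
      expect_equal(traceLogLikelihood(m, tr, 38, 0, 8),
                   bruteForceLogLik(m, x, 38, 0, 8), tolerance = 1e-8)
    }
  }
})

test_that("likelihood is invariant to a common shift of trace and baseline", {
  m <- coupledGatingModel(2, 0.1, 0.3, 0.3)
  x <- c(1, 40, 75, 39, 2, 0)
  l1 <- traceLogLikelihood(m, calciumTrace(x, 0.01), 38, 0, 8)
  l2 <- traceLogLikelihood(m, calciumTrace(x + 123, 0.01), 38, 123, 8)
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("kappa estimator recovers coupled and independent gating", {
  # fully coupled: kappa-hat > 0.9 (occupancy path, fast)
  kapHi <- vapply(1:10, function(i) {
    occ <- simulateOccupancy(coupledGatingModel(2, 0.03, 0.3, 1), 2000,
                             seed = 500 + i)
    kappa(estimateKappa(occ, nChannels = 2))
  }, numeric(1))
  expect_gt(mean(kapHi), 0.9)

  # independent gating: mean kappa-hat below the 0.1 coupling threshold,
  # classified uncoupled
  fits <- lapply(1:10, function(i) {
    occ <- simulateOccupancy(coupledGatingModel(2, 0.03, 0.3, 0), 2000,
                             seed = 600 + i)
    estimateKappa(occ, nChannels = 2)
  })
  kapLo <- vapply(fits, kappa, numeric(1))
  expect_lt(mean(kapLo), 0.1)
  expect_gt(mean(!vapply(fits, isCoupled, logical(1))), 0.5)
})

test_that("kappa estimate error shrinks with trace length", {
  err <- function(len, kapTrue) {
    mean(vapply(1:6, function(i) {
      occ <- simulateOccupancy(coupledGatingModel(2, 0.03, 0.3, kapTrue),
                               len, seed = 700 + 13 * i)
      abs(kappa(estimateKappa(occ, 2)) - kapTrue)
    }, numeric(1)))
  }
  for (kapTrue in c(0, 0.2, 0.5, 1))
    expect_lt(err(10000, kapTrue), err(1000, kapTrue) + 0.02)
})

test_that("degenerate constant records return kappa 0 with a flag", {
  occ <- occupancyTrace(rep(0L, 200), 2, 0.01)
  fit <- estimateKappa(occ, 2)
  expect_equal(kappa(fit), 0)
  expect_false(isCoupled(fit))
  expect_true("no transitions" %in% fit@flags)
})

test_that("model validity rejects out-of-range parameters", {
  expect_error(coupledGatingModel(0, 0.1, 0.1), "nChannels")
  expect_error(coupledGatingModel(2, 0, 0.1), "pOpen")
  expect_error(coupledGatingModel(2, 0.1, 1), "pClose")
  # kappa outside [0,1] is clipped by the constructor
  expect_equal(kappa(coupledGatingModel(2, 0.1, 0.1, 1.7)), 1)
})
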