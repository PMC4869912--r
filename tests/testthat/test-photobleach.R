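test_that("preprocessing removes background and keeps spots", {
  # uniform stack: detection image ~ zero
  flat <- imageStack(array(100, dim = c(32, 32, 6)), 100, 1 / 30)
  det <- preprocessStack(flat)
  expect_lt(max(abs(det)), 1e-9)

  # a bright Gaussian spot survives the band-pass with its peak in place
  img <- array(10, dim = c(32, 32, 6))
  g <- outer(dnorm(1:32, 16, 1.5), dnorm(1:32, 20, 1.5))
  for (f in 1:6) img[, , f] <- img[, , f] + 5e3 * g
  spot <- imageStack(img, 100, 1 / 30)
  detS <- preprocessStack(spot)
  pk <- which(detS == max(detS), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(16, 20))
  expect_gt(max(detS), 0)

  # constant offset leaves the detection image unchanged
  spot2 <- imageStack(img + 500, 100, 1 / 30)
  expect_equal(preprocessStack(spot2), detS, tolerance = 1e-6)

  expect_error(preprocessStack(imageStack(array(1, c(8, 8, 3)), 100, 1)),
               "at least 5")
})

test_that("spot detection returns anchored 4x4 ROIs", {
  blank <- matrix(0, 32, 32)
  expect_equal(nrow(detectSpots(blank, threshold = 1)), 0)

  two <- matrix(0, 32, 32)
  two[10, 10] <- 10; two[24, 20] <- 8
  rois <- detectSpots(two, threshold = 1)
  expect_equal(nrow(rois), 2)
  expect_setequal(rois$peak_row, c(10, 24))
  # peak sits at window position (2, 2)
  expect_equal(rois$row0, rois$peak_row - 1L)
  expect_equal(rois$col0, rois$peak_col - 1L)

  # merged spots < 2 px apart collapse to one ROI
  close2 <- matrix(0, 32, 32)
  close2[15, 15] <- 10; close2[15, 16] <- 9
  expect_equal(nrow(detectSpots(close2, threshold = 1)), 1)
})

test_that("ROI z-profiles are window sums and linear in the stack", {
  arr <- array(rnorm(16 * 16 * 20, 100, 1), dim = c(16, 16, 20))
  st <- imageStack(pmax(arr, 0), 100, 1 / 30)
  roi <- data.frame(row0 = 5, col0 = 7)
  z <- traceValues(extractTrace(st, roi))
  expect_equal(z[3], sum(st@data[5:8, 7:10, 3]))

  # linearity under stack addition
  st2 <- imageStack(st@data * 2, 100, 1 / 30)
  expect_equal(traceValues(extractTrace(st2, roi)), 2 * z)

  expect_error(extractTrace(st, data.frame(row0 = 15, col0 = 1)), "bounds")
})

test_that("step counter is exact on noiseless staircases of 1-10 steps", {
  set.seed(61)
  for (ns in 1:10) {
    frames <- sort(sample(seq(20, 480, by = 6), ns))
    x <- makeStaircase(500, frames)
    fit <- countSteps(bleachTrace(x, 1 / 30))
    expect_equal(nSteps(fit), ns)
    expect_equal(fit@stepFrames, as.integer(frames + 1L))
    expect_true(all(fit@stepAmplitudes < 0))
  }
})

test_that("step count is invariant to positive scaling with auto minStep", {
  x <- makeStaircase(300, c(60, 150, 220), step = 80)
  f1 <- countSteps(x)
  f2 <- countSteps(x * 7.3)
  expect_equal(nSteps(f1), nSteps(f2))
  expect_equal(f1@stepFrames, f2@stepFrames)
})

test_that("flat noisy traces rarely produce spurious steps", {
  set.seed(62)
  fp <- mean(replicate(100, nSteps(countSteps(rnorm(300, 100, 10))) > 0))
  expect_lte(fp, 0.05)
})

test_that("step counting stays >= 90% exact at step-SNR 3", {
  set.seed(63)
  hits <- replicate(200, {
    ns <- sample(1:6, 1)
    frames <- sort(sample(seq(30, 460, by = 10), ns))
    x <- makeStaircase(500, frames, step = 90) + rnorm(500, 0, 30)
    nSteps(countSteps(x)) == ns
  })
  expect_gte(mean(hits), 0.9)
})

test_that("end-to-end bleach pipeline recovers planted step counts", {
  set.seed(64)
  forced <- lapply(1:12, function(i)
    sort(sample(seq(40, 520, by = 25), sample(2:5, 1))))
  bp <- bleachPreset(stepAmplitude = 120, noiseSd = 4, nFrames = 600,
                     forcedBleachFrames = forced)
  sim <- makeBleachStack(bp, nSpots = 12, imageSize = 64, seed = 64)
  det <- preprocessStack(sim$stack)
  rois <- detectSpots(det)
  expect_gt(nrow(rois), 0)
  # match each ROI to its planted spot and compare step counts
  correct <- 0; total <- 0
  for (r in seq_len(nrow(rois))) {
    d <- (sim$spots$row - rois$peak_row[r]) ^ 2 +
         (sim$spots$col - rois$peak_col[r]) ^ 2
    sp <- which.min(d)
    if (d[sp] > 9) next
    truth <- length(sim$bleachFrames[[sp]])
    fit <- countSteps(extractTrace(sim$stack, rois[r, ]))
    total <- total + 1
    if (nSteps(fit) == truth) correct <- correct + 1
  }
  expect_gt(total, 5)
  expect_gte(correct / total, 0.9)
})

test_that("step-count summaries report the stoichiometry distribution", {
  mkFit <- function(n) {
    frames <- if (n > 0) as.integer(seq(10, 90, length.out = n)) else integer()
    new("StepFit", nSteps = as.integer(n), stepFrames = frames,
        stepAmplitudes = rep(-1, n), residual = 0,
        levels = seq(n, 0) * 1.0, flags = character())
  }
  same <- lapply(1:5, function(i) mkFit(3))
  s <- summarizeStepCounts(same)
  expect_equal(s$mean, 3)
  expect_equal(s$sem, 0)

  mix <- c(lapply(1:2, function(i) mkFit(1)),
           lapply(1:5, function(i) mkFit(6)),
           lapply(1:3, function(i) mkFit(3)))
  sm <- summarizeStepCounts(mix)
  expect_equal(sm$fracSingle, 0.2)
  expect_equal(sm$fracGe5, 0.5)
  # empty bins are preserved in the histogram
  expect_equal(as.integer(sm$histogram[["2"]]), 0)
  expect_equal(sum(sm$histogram), 10)
})
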