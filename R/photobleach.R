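## Step-photobleaching pipeline: detection-image preprocessing, spot ROI
## selection, z-profile extraction and automated step counting.

## Separable Gaussian blur with reflecting edges.
.gaussBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  halfw <- max(1L, ceiling(3 * sigma))
  kern <- dnorm(-halfw:halfw, sd = sigma)
  kern <- kern / sum(kern)
  pad <- function(x) c(rev(x[seq_len(halfw)]), x,
                       rev(x[length(x) - seq_len(halfw) + 1L]))
  smooth1 <- function(x) {
    y <- stats::filter(pad(x), kern, sides = 2)
    as.numeric(y[(halfw + 1L):(halfw + length(x))])
  }
  img <- apply(img, 2, smooth1)
  t(apply(img, 1, smooth1))
}

#' Preprocess a photobleaching stack into a detection image
#'
#' Mirrors the standard spot-finding recipe: average the first 5 frames,
#' remove smooth background with a rolling-ball (grayscale disk opening,
#' default radius 10 px), then band-pass spatially as the difference of two
#' Gaussian smoothings whose sigmas match the stated 2 px (low-pass) and
#' 5 px (high-pass) cutoffs.  Constant offsets cancel in both stages.
#'
#' @param stack an [ImageStack-class] with >= 5 frames.
#' @param ballRadius rolling-ball radius in px.
#' @param lowCutoff,highCutoff band-pass cutoffs in px.
#' @return numeric matrix (the detection image).
#' @export
preprocessStack <- function(stack, ballRadius = 10, lowCutoff = 2,
                            highCutoff = 5) {
  stopifnot(is(stack, "ImageStack"))
  d <- stack@data
  if (dim(d)[3] < 5) stop("stack must have at least 5 frames")
  avg <- apply(d[, , 1:5, drop = FALSE], c(1, 2), mean)
  bg <- .cg_disk_opening(avg, as.integer(ballRadius))
  fg <- avg - bg
  .gaussBlur(fg, lowCutoff / 2) - .gaussBlur(fg, highCutoff / 2)
}

#' Detect spots and build 4x4 ROIs
#'
#' Thresholds the detection image ("auto" = mean + 3 SD), labels 8-connected
#' components, finds the peak pixel of each, and anchors a 4x4 ROI with the
#' peak at window position (2, 2) — the fixed convention for an even
#' window "centered" on a pixel.  Components whose ROI would leave the image
#' are dropped.
#'
#' @param detectionImage matrix from [preprocessStack()].
#' @param threshold "auto" or a numeric intensity cutoff.
#' @return data.frame with columns peak_row, peak_col, row0, col0 (top-left
#'   of the 4x4 window); zero rows when nothing is found.
#' @export
detectSpots <- function(detectionImage, threshold = "auto") {
  img <- detectionImage
  if (identical(threshold, "auto"))
    threshold <- mean(img) + 3 * sd(img)
  mask <- img > threshold
  empty <- data.frame(peak_row = integer(), peak_col = integer(),
                      row0 = integer(), col0 = integer())
  if (!any(mask)) return(empty)
  lab <- .cg_label_components(mask)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  out <- lapply(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    peak <- px[which.max(img[px]), , drop = TRUE]
    r0 <- peak[1] - 1L; c0 <- peak[2] - 1L   # peak at window (2, 2)
    if (r0 < 1L || c0 < 1L || r0 + 3L > nrow(img) || c0 + 3L > ncol(img))
      return(NULL)
    data.frame(peak_row = peak[1], peak_col = peak[2], row0 = r0, col0 = c0)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Extract the z-profile of one ROI
#'
#' Per-frame sum of the 4x4 window: the intensity-versus-time trace used
#' for step counting.
#'
#' @param stack an [ImageStack-class].
#' @param roi one row of the data.frame from [detectSpots()] (needs row0,
#'   col0).
#' @return a [BleachTrace-class] of length nframes.
#' @export
extractTrace <- function(stack, roi) {
  stopifnot(is(stack, "ImageStack"))
  r0 <- roi$row0[1]; c0 <- roi$col0[1]
  d <- stack@data
  if (r0 < 1 || c0 < 1 || r0 + 3 > dim(d)[1] || c0 + 3 > dim(d)[2])
    stop("ROI out of image bounds")
  vals <- apply(d[r0:(r0 + 3), c0:(c0 + 3), , drop = FALSE], 3, sum)
  bleachTrace(vals, stack@dt)
}

## Greedy top-down piecewise-constant segmentation.  Returns breakpoints
## (last index of each left segment) ordered by addition, with the RSS after
## each addition.
.greedySegments <- function(x, maxBreaks, minSegLen = 2L) {
  n <- length(x)
  bounds <- c(0L, n)          # segment boundaries (cumulative counts)
  breaks <- integer()
  rssTrace <- numeric()
  segCost <- function(i, j) {  # RSS of x[(i+1)..j]
    seg <- x[(i + 1L):j]
    sum(seg ^ 2) - sum(seg) ^ 2 / length(seg)
  }
  for (iter in seq_len(maxBreaks)) {
    bestGain <- -Inf; bestAt <- NA_integer_
    bs <- sort(bounds)
    for (s in seq_len(length(bs) - 1L)) {
      i <- bs[s]; j <- bs[s + 1L]
      if (j - i < 2L * minSegLen) next
      seg <- x[(i + 1L):j]
      m <- length(seg)
      csum <- cumsum(seg); csq <- cumsum(seg ^ 2)
      tot <- csq[m] - csum[m] ^ 2 / m
      cut <- minSegLen:(m - minSegLen)
      left <- csq[cut] - csum[cut] ^ 2 / cut
      right <- (csq[m] - csq[cut]) -
        (csum[m] - csum[cut]) ^ 2 / (m - cut)
      gains <- tot - (left + right)
      w <- which.max(gains)
      if (gains[w] > bestGain) {
        bestGain <- gains[w]
        bestAt <- i + cut[w]
      }
    }
    if (!is.finite(bestGain) || is.na(bestAt)) break
    breaks <- c(breaks, bestAt)
    bounds <- c(bounds, bestAt)
    bs <- sort(bounds)
    rss <- sum(vapply(seq_len(length(bs) - 1L),
                      function(s) segCost(bs[s], bs[s + 1L]), numeric(1)))
    rssTrace <- c(rssTrace, rss)
  }
  list(breaks = breaks, rss = rssTrace)
}

#' Count photobleaching steps in a z-profile
#'
#' Automated replacement for manual step counting: greedy top-down
#' piecewise-constant fitting (each iteration adds the breakpoint that most
#' reduces the squared error), stopped by a Schwarz-type criterion
#' \eqn{T \log(RSS/T) + 2 m \log T} over the number of breakpoints m.  Only
#' downward steps with magnitude at least \code{minStep} are retained;
#' \code{"auto"} sets minStep to half the median step magnitude of the
#' first fit.
#'
#' @param trace a [BleachTrace-class] (or numeric vector) with >= 50
#'   frames.
#' @param minStep "auto" or a positive amplitude threshold (AU).
#' @param maxSteps cap on fitted steps (default 20); exceeding it sets the
#'   "max_steps_reached" flag and returns the best capped fit.
#' @return a [StepFit-class].
#' @export
countSteps <- function(trace, minStep = "auto", maxSteps = 20) {
  x <- if (is(trace, "BleachTrace")) trace@values else as.numeric(trace)
  n <- length(x)
  if (n < 50) stop("trace must have at least 50 frames")

  seg <- .greedySegments(x, maxBreaks = maxSteps + 5L)
  rss0 <- sum((x - mean(x)) ^ 2)
  eps <- max(1e-12 * max(rss0, 1), .Machine$double.xmin)
  bicOf <- function(m, rss) n * log(max(rss, eps) / n) + 2 * m * log(n)
  bics <- c(bicOf(0, rss0),
            vapply(seq_along(seg$rss),
                   function(m) bicOf(m, seg$rss[m]), numeric(1)))
  mBest <- which.min(bics) - 1L
  flags <- character()
  if (mBest > maxSteps) { mBest <- maxSteps; flags <- "max_steps_reached" }
  keepBreaks <- sort(seg$breaks[seq_len(mBest)])

  levelsOf <- function(brk) {
    bs <- c(0L, brk, n)
    vapply(seq_len(length(bs) - 1L),
           function(s) mean(x[(bs[s] + 1L):bs[s + 1L]]), numeric(1))
  }
  lv <- levelsOf(keepBreaks)
  amps <- diff(lv)

  if (identical(minStep, "auto"))
    minStep <- if (length(amps)) 0.5 * median(abs(amps)) else 0

  keep <- amps < 0 & abs(amps) >= minStep
  brk <- keepBreaks[keep]
  lv <- levelsOf(brk)
  amps <- diff(lv)
  bs <- c(0L, brk, n)
  rss <- sum(vapply(seq_len(length(bs) - 1L), function(s) {
    segx <- x[(bs[s] + 1L):bs[s + 1L]]
    sum((segx - mean(segx)) ^ 2)
  }, numeric(1)))

  # step frame = first frame of the lower level
  new("StepFit", nSteps = length(brk), stepFrames = as.integer(brk + 1L),
      stepAmplitudes = as.numeric(amps), residual = rss,
      levels = lv, flags = flags)
}

#' Summarize step counts over many spots
#'
#' @param fits list of [StepFit-class].
#' @return list with \code{histogram} (named counts over 0..max steps,
#'   empty bins preserved), \code{mean}, \code{sem}, \code{n},
#'   \code{fracSingle} (fraction with exactly 1 step) and \code{fracGe5}
#'   (fraction with >= 5 steps).
#' @export
summarizeStepCounts <- function(fits) {
  if (!length(fits)) stop("need at least one step fit")
  counts <- vapply(fits, nSteps, integer(1))
  tab <- table(factor(counts, levels = 0:max(counts)))
  list(histogram = tab,
       mean = mean(counts),
       sem = if (length(counts) > 1) sd(counts) / sqrt(length(counts)) else 0,
       n = length(counts),
       fracSingle = mean(counts == 1L),
       fracGe5 = mean(counts >= 5L))
}
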