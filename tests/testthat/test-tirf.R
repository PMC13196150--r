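gaussSpot <- function(n, cy, cx, sigma = 1.5, amp = 100) {
  outer(1:n, 1:n, function(y, x)
    amp * exp(-((y - cy)^2 + (x - cx)^2) / (2 * sigma^2)))
}

test_that("voronoiOtsuLabel separates well-spaced and merged spots", {
  # two spots 20 px apart -> 2 labels, each containing its true centre
  pl <- gaussSpot(41, 11, 21) + gaussSpot(41, 31, 21)
  lm <- voronoiOtsuLabel(pl, 1, 1.5)
  expect_equal(nLabels(lm), 2)
  expect_equal(labelData(lm)[11, 21], 1L)
  expect_equal(labelData(lm)[31, 21], 2L)
  # one spot -> 1 label
  expect_equal(nLabels(voronoiOtsuLabel(gaussSpot(21, 11, 11), 1, 1.5)), 1)
  # constant plane -> empty map, not an error
  expect_equal(nLabels(voronoiOtsuLabel(matrix(3, 15, 15), 1, 1.5)), 0)
  expect_error(voronoiOtsuLabel(matrix(-1, 5, 5), 1, 1.5), "non-negative")
})

test_that("merged spots are split along the midline (nearest-seed rule)", {
  pl <- gaussSpot(21, 10, 9, sigma = 0.8) + gaussSpot(21, 10, 12, sigma = 0.8)
  lm <- voronoiOtsuLabel(pl, 1, 1.5)
  expect_equal(nLabels(lm), 2)
  lab <- labelData(lm)
  expect_equal(lab[10, 9], 1L)
  expect_equal(lab[10, 12], 2L)
  # every foreground pixel belongs to the nearest seed (tie -> lower label)
  fg <- which(lab > 0, arr.ind = TRUE)
  d1 <- (fg[, 1] - 10)^2 + (fg[, 2] - 9)^2
  d2 <- (fg[, 1] - 10)^2 + (fg[, 2] - 12)^2
  expected <- ifelse(d1 <= d2, 1L, 2L)
  expect_equal(lab[fg], expected)
})

test_that("cell masks pass through externally or fall back to thresholding", {
  sim <- simulateTirfSeries(list(nFrames = 1, width = 128, height = 128,
                                 nReference = 25, nQuery = 25), seed = 3)
  r <- getPlane(sim$stack, 1, channel = 2)
  ext <- matrix(TRUE, 128, 128)
  expect_identical(cellMaskForFrame(r, "external", ext), ext)
  expect_error(cellMaskForFrame(r, "external", matrix(TRUE, 4, 4)), "shape")
  expect_error(cellMaskForFrame(r, "manual"), "requires an external mask")
  auto <- cellMaskForFrame(r, "threshold_fallback", medianRadius = 4)
  truthMask <- sim$truth@rasters$cellMask
  expect_gte(sum(auto & truthMask) / sum(truthMask), 0.9)
})

test_that("overlap scores are covered-pixel fractions", {
  lab <- matrix(0L, 10, 10)
  lab[2:3, 2:3] <- 1L                                 # 4 px
  lab[6, 1:10] <- 2L                                  # 10 px
  lab[9:10, 9:10] <- 3L                               # 4 px
  lm <- new("LabelMap", data = lab, nLabels = 3L)
  ref <- matrix(FALSE, 10, 10)
  ref[1:4, 1:4] <- TRUE                               # covers label 1 fully
  ref[6, 1:5] <- TRUE                                 # covers half of label 2
  sc <- overlapScores(lm, ref)
  expect_equal(sc$score, c(1, 0.5, 0))
  expect_equal(sc$area, c(4L, 10L, 4L))
  expect_equal(sc$centroidY[2], 5)                    # 0-based centroid
  empty <- new("LabelMap", data = matrix(0L, 5, 5), nLabels = 0L)
  expect_equal(nrow(overlapScores(empty, matrix(TRUE, 5, 5))), 0)
})

test_that("overlap classes partition [0,1] at the 0.5/0.01 cut-offs", {
  got <- classifyOverlap(c(0, 0.005, 0.01, 0.3, 0.5, 0.75, 1))
  expect_equal(as.character(got),
               c("non", "non", "partial", "partial",
                 "colocalized", "colocalized", "colocalized"))
  expect_error(classifyOverlap(1.2), "0, 1")
  expect_error(colocConfig(cutLow = 0.6, cutHigh = 0.5), "cutLow")
})

test_that("query vesicles placed exactly on reference vesicles give ratio 1", {
  sim <- simulateTirfSeries(list(nFrames = 2, width = 128, height = 128,
                                 nReference = 30, nQuery = 30,
                                 colocFraction = 1, jitterSigmaPx = 0,
                                 poissonNoise = FALSE, readNoiseSd = 0),
                            seed = 5)
  res <- analyzeTirfSeries(sim$stack)
  expect_true(all(res$frames$colocRatio == 1))
})

test_that("an empty reference channel yields all-zero scores", {
  sim <- simulateTirfSeries(list(nFrames = 2, width = 96, height = 96,
                                 nReference = 0, nQuery = 20,
                                 colocFraction = 0, cellBackground = 0,
                                 poissonNoise = FALSE, readNoiseSd = 0),
                            seed = 6)
  masks <- array(TRUE, c(2, 96, 96))
  cfg <- colocConfig(maskStrategy = "external")
  res <- analyzeTirfSeries(sim$stack, cfg, masks)
  expect_true(all(res$vesicles$score == 0))
  expect_true(all(res$frames$colocRatio == 0))
})

test_that("counts are conserved and scores invariant to intensity rescaling", {
  sim <- simulateTirfSeries(list(nFrames = 2, width = 128, height = 128,
                                 nReference = 30, nQuery = 30), seed = 8)
  res <- analyzeTirfSeries(sim$stack)
  expect_true(all(res$frames$nColoc + res$frames$nPartial + res$frames$nNon
                  == res$frames$nTotal))
  d <- stackData(sim$stack)
  d[, 1, , ] <- d[, 1, , ] * 3                        # rescale query channel
  scaled <- ImageStack(d, c("time", "channel", "y", "x"), 0.1, 10)
  res2 <- analyzeTirfSeries(scaled)
  expect_equal(res2$vesicles$score, res$vesicles$score)
  expect_equal(res2$vesicles$colocClass, res$vesicles$colocClass)
})

test_that("reciprocal direction matches forward on symmetric input", {
  sim <- simulateTirfSeries(list(nFrames = 2, width = 128, height = 128,
                                 nReference = 25, nQuery = 25), seed = 12)
  d <- stackData(sim$stack)
  d[, 2, , ] <- d[, 1, , ]                            # identical channels
  sym <- ImageStack(d, c("time", "channel", "y", "x"), 0.1, 10)
  res <- analyzeTirfSeries(sym, colocConfig(reciprocal = TRUE))
  expect_equal(res$reciprocal$nColoc / res$reciprocal$nTotal,
               res$frames$colocRatio)
})

test_that("frames with an empty cell mask are skipped with a warning", {
  arr <- array(100, c(2, 2, 64, 64))
  set.seed(1)
  arr[2, , , ] <- arr[2, , , ] + rpois(2 * 64 * 64, 50)
  stack <- ImageStack(arr, c("time", "channel", "y", "x"), 0.1, 10)
  masks <- array(FALSE, c(2, 64, 64))
  masks[2, 10:50, 10:50] <- TRUE
  cfg <- colocConfig(maskStrategy = "external")
  expect_warning(res <- analyzeTirfSeries(stack, masks = masks, config = cfg),
                 "empty cell mask")
  expect_equal(res$skippedFrames, 0L)
  expect_equal(res$frames$frame, 1L)
  expect_error(analyzeTirfSeries(stack, masks = NULL, config = cfg),
               "missing external mask")
})

test_that("a two-channel time axis is required", {
  s <- ImageStack(array(1, c(3, 3, 8, 8)), "tzyx")
  expect_error(analyzeTirfSeries(s), "channel")
  s3 <- ImageStack(array(1, c(2, 3, 8, 8)), "tcyx")
  expect_error(analyzeTirfSeries(s3), "2 channels")
})
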