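test_that("track metrics follow the 3-4-5 example and the accumulation oracle", {
  # (0; 0,0) -> (1; 3,4) px at 0.1 um/px, 10 s/frame
  m <- trackMetrics(data.frame(frame = 0:1, y = c(0, 3), x = c(0, 4)),
                    pixelSizeUm = 0.1, frameIntervalS = 10)
  expect_equal(m$displacementUm, 0.5)
  expect_equal(m$meanSpeedUmS, 0.05)
  # out-and-back: displacement 0, path > 0
  ob <- trackMetrics(data.frame(frame = 0:2, y = c(0, 5, 0), x = c(0, 0, 0)),
                     0.1, 10)
  expect_equal(ob$displacementUm, 0)
  expect_gt(ob$pathLengthUm, 0)
  # single point: zero displacement, undefined mean speed
  one <- trackMetrics(data.frame(frame = 3, y = 1, x = 2), 0.1, 10)
  expect_equal(one$displacementUm, 0)
  expect_true(is.na(one$meanSpeedUmS))
  # random 20-point track equals a step-by-step loop oracle
  set.seed(31)
  pts <- data.frame(frame = sort(sample(0:40, 20)),
                    y = runif(20, 0, 50), x = runif(20, 0, 50))
  m20 <- trackMetrics(pts, 0.2, 5)
  path <- 0; speeds <- c()
  for (i in 2:20) {
    d <- sqrt((pts$y[i] - pts$y[i - 1])^2 + (pts$x[i] - pts$x[i - 1])^2) * 0.2
    path <- path + d
    speeds <- c(speeds, d / ((pts$frame[i] - pts$frame[i - 1]) * 5))
  }
  expect_equal(m20$pathLengthUm, path)
  expect_equal(m20$meanSpeedUmS, mean(speeds))
  expect_lte(m20$displacementUm, m20$pathLengthUm)
})

test_that("well-separated moving vesicles are linked into full tracks", {
  det <- do.call(rbind, lapply(0:9, function(f)
    data.frame(frame = f, y = c(10, 60) + f, x = c(10, 60))))
  ts <- linkDetections(det, trackingConfig(maxLinkDistanceUm = 0.5),
                       pixelSizeUm = 0.1, frameIntervalS = 10)
  m <- trackMetricsTable(ts)
  expect_equal(nrow(m), 2)
  expect_equal(m$nPoints, c(10L, 10L))
  # single detection in one frame -> one 1-point track
  ts1 <- linkDetections(data.frame(frame = 0, y = 5, x = 5))
  expect_equal(trackMetricsTable(ts1)$nPoints, 1L)
  # empty input -> empty output
  ts0 <- linkDetections(data.frame(frame = integer(), y = numeric(),
                                   x = numeric()))
  expect_equal(nrow(trackPoints(ts0)), 0)
})

test_that("links beyond the distance gate are refused", {
  # two detections crossing with steps larger than the gate -> 4 tracks
  det <- data.frame(frame = c(0, 0, 1, 1),
                    y = c(0, 0, 0, 0), x = c(0, 10, 6, 4))
  ts <- linkDetections(det, trackingConfig(maxLinkDistanceUm = 0.3),
                       pixelSizeUm = 0.1, frameIntervalS = 10)
  expect_equal(nrow(trackMetricsTable(ts)), 4)
})

test_that("frame gaps are bridged up to maxFrameGap with true elapsed time", {
  det <- data.frame(frame = c(0, 2), y = c(0, 0), x = c(0, 2))
  ts <- linkDetections(det, trackingConfig(maxLinkDistanceUm = 0.5,
                                           maxFrameGap = 2),
                       pixelSizeUm = 0.1, frameIntervalS = 10)
  m <- trackMetricsTable(ts)
  expect_equal(nrow(m), 1)
  expect_equal(m$meanSpeedUmS, 0.2 / 20)   # 2 px over 2 frames of 10 s
  tsNo <- linkDetections(det, trackingConfig(maxLinkDistanceUm = 0.5,
                                             maxFrameGap = 1),
                         pixelSizeUm = 0.1, frameIntervalS = 10)
  expect_equal(nrow(trackMetricsTable(tsNo)), 2)
})

test_that("linking is invariant to detection order within frames", {
  set.seed(32)
  base <- do.call(rbind, lapply(0:5, function(f)
    data.frame(frame = f, y = runif(8, 0, 100) , x = runif(8, 0, 100))))
  canon <- function(ts) {
    p <- trackPoints(ts)
    unname(sort(vapply(split(p, p$trackId), function(tr)
      paste(tr$frame, round(tr$y, 9), round(tr$x, 9), collapse = ";"),
      character(1))))
  }
  ts1 <- linkDetections(base, trackingConfig(maxLinkDistanceUm = 2))
  shuffled <- do.call(rbind, lapply(split(base, base$frame),
                                    function(d) d[sample.int(nrow(d)), ]))
  ts2 <- linkDetections(shuffled, trackingConfig(maxLinkDistanceUm = 2))
  expect_equal(canon(ts1), canon(ts2))
})

test_that("displacement taxonomy counts are conserved and boundary-stable", {
  # displacements {0.2, 0.5, 1.0, 2.0} um at threshold 0.67 -> 2 + 2
  mk <- function(dUm, id) data.frame(frame = 0:1, y = 0,
                                     x = c(0, dUm / 0.1) + 1000 * id)
  det <- do.call(rbind, Map(mk, c(0.2, 0.5, 1.0, 2.0), 1:4))
  ts <- linkDetections(det, trackingConfig(maxLinkDistanceUm = 3),
                       pixelSizeUm = 0.1, frameIntervalS = 10)
  cl <- classifyTracks(ts, 0.67)
  expect_equal(unname(cl$counts), c(2L, 2L, 4L))
  # displacement exactly at the threshold counts as stationary
  tsb <- linkDetections(data.frame(frame = 0:1, y = 0, x = c(0, 6.7)),
                        trackingConfig(maxLinkDistanceUm = 1),
                        pixelSizeUm = 0.1, frameIntervalS = 10)
  clb <- classifyTracks(tsb, 0.67)
  expect_equal(as.character(clb$metrics$motionClass), "stationary")
  # empty input -> all counts zero
  cl0 <- classifyTracks(linkDetections(data.frame(frame = integer(),
                                                  y = numeric(),
                                                  x = numeric())))
  expect_equal(unname(cl0$counts), c(0L, 0L, 0L))
})

test_that("the simulated cohort is recovered exactly end to end", {
  st <- simulateTracks(30, 12, 0.67, seed = 7)
  ts <- linkDetections(st$detections, trackingConfig(),
                       pixelSizeUm = 0.1, frameIntervalS = 1)
  cl <- classifyTracks(ts)
  expect_equal(unname(cl$counts), c(30L, 12L, 42L))
  m <- cl$metrics
  expect_true(all(m$displacementUm <= m$pathLengthUm + 1e-9))
  # recovered displacements match the generator truth as multisets
  expect_equal(sort(m$displacementUm),
               sort(st$truth@records$displacementUm),
               tolerance = 1e-6)
})
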