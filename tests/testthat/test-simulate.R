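test_that("generators are bit-identical for the same parameters and seed", {
  a <- simulateTirfSeries(list(nFrames = 2, width = 64, height = 64,
                               nReference = 10, nQuery = 10), seed = 5)
  b <- simulateTirfSeries(list(nFrames = 2, width = 64, height = 64,
                               nReference = 10, nQuery = 10), seed = 5)
  expect_identical(stackData(a$stack), stackData(b$stack))
  expect_identical(a$truth@records, b$truth@records)
  c1 <- simulateConfocalCell(list(width = 64, height = 64, ringWidth = 6),
                             seed = 3)
  c2 <- simulateConfocalCell(list(width = 64, height = 64, ringWidth = 6),
                             seed = 3)
  expect_identical(stackData(c1$stack), stackData(c2$stack))
  t1 <- simulateTracks(5, 3, seed = 9)
  t2 <- simulateTracks(5, 3, seed = 9)
  expect_identical(t1$detections, t2$detections)
  # a different seed changes the noise
  c3 <- simulateConfocalCell(list(width = 64, height = 64, ringWidth = 6),
                             seed = 4)
  expect_false(identical(stackData(c1$stack), stackData(c3$stack)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulateTracks(3, 2, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("the colocalized fraction is exact in the ground truth", {
  for (f in c(0, 0.3, 1)) {
    sim <- simulateTirfSeries(list(nFrames = 1, width = 96, height = 96,
                                   nReference = 20, nQuery = 20,
                                   colocFraction = f), seed = 2)
    q <- subset(sim$truth@records, channel == "query")
    expect_equal(mean(q$colocalized), f)
  }
  expect_error(simulateTirfSeries(list(colocFraction = 1.5)), "0, 1")
  expect_error(simulateTirfSeries(list(bogus = 1)), "unknown parameter")
})

test_that("non-colocalized query spots stay 3 psf away from reference spots", {
  sim <- simulateTirfSeries(list(nFrames = 3, width = 128, height = 128,
                                 nReference = 25, nQuery = 25,
                                 colocFraction = 0), seed = 4)
  rec <- sim$truth@records
  psf <- sim$truth@params$psfSigma
  for (f in unique(rec$frame)) {
    q <- rec[rec$frame == f & rec$channel == "query", ]
    r <- rec[rec$frame == f & rec$channel == "reference", ]
    dmin <- min(sqrt(outer(q$y, r$y, "-")^2 + outer(q$x, r$x, "-")^2))
    expect_gte(dmin, 3 * psf)
  }
})

test_that("fully colocalized noiseless spots sit on reference footprints", {
  sim <- simulateTirfSeries(list(nFrames = 2, width = 96, height = 96,
                                 nReference = 15, nQuery = 15,
                                 colocFraction = 1, jitterSigmaPx = 0,
                                 poissonNoise = FALSE, readNoiseSd = 0),
                            seed = 8)
  rec <- sim$truth@records
  psf <- sim$truth@params$psfSigma
  for (f in unique(rec$frame)) {
    q <- rec[rec$frame == f & rec$channel == "query", ]
    r <- rec[rec$frame == f & rec$channel == "reference", ]
    dmin <- apply(sqrt(outer(q$y, r$y, "-")^2 + outer(q$x, r$x, "-")^2),
                  1, min)
    expect_true(all(dmin <= 3 * psf))      # inside a reference footprint
  }
})

test_that("confocal truth rasters satisfy their stated identities", {
  sim <- simulateConfocalCell(list(membraneRatio = 1, poissonNoise = FALSE,
                                   readNoiseSd = 0), seed = 1)
  tr <- sim$truth
  # ratio 1: noiseless image is uniform inside the cell
  inside <- tr@rasters$noiselessProjection[tr@rasters$cellMask]
  expect_equal(length(unique(round(inside, 9))), 1)
  # masks partition: ring = cell minus inner
  expect_identical(tr@rasters$ringMask,
                   tr@rasters$cellMask & !tr@rasters$innerMask)
  # stack data obeys ImageStack invariants by construction
  expect_true(validObject(sim$stack))
  expect_error(simulateConfocalCell(list(ringWidth = 80)), "wider")
})

test_that("track cohorts honour their displacement classes exactly", {
  st <- simulateTracks(12, 7, 0.67, seed = 5)
  tr <- st$truth@records
  expect_equal(sum(tr$motionClass == "stationary"), 12)
  expect_equal(sum(tr$motionClass == "dynamic"), 7)
  expect_true(all(tr$displacementUm[tr$motionClass == "stationary"]
                  < 0.8 * 0.67))
  expect_true(all(tr$displacementUm[tr$motionClass == "dynamic"]
                  > 1.2 * 0.67))
  # true point displacements equal the recorded ones
  pts <- st$truth@rasters$points
  for (id in unique(pts$trackId)) {
    p <- pts[pts$trackId == id, ]
    d <- sqrt((p$y[nrow(p)] - p$y[1])^2 + (p$x[nrow(p)] - p$x[1])^2) * 0.1
    expect_equal(d, tr$displacementUm[tr$trackId == id], tolerance = 1e-9)
  }
  # empty cohort
  e <- simulateTracks(0, 0, seed = 1)
  expect_equal(nrow(e$detections), 0)
})
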