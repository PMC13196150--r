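disk <- function(n, r, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  outer(1:n, 1:n, function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

test_that("fillHoles fills enclosed background only", {
  d <- disk(21, 7)
  expect_equal(fillHoles(d), d)                      # no holes
  ring <- d & !disk(21, 6)                           # 1-px thick ring
  expect_equal(fillHoles(ring), d)
  # random blobs with punched holes equal the flood-fill oracle
  for (seed in c(2, 5)) {
    m <- randomBlobMask(seed, 40)
    m[10:12, 10:12] <- FALSE; m[25, 30] <- FALSE; m[30:31, 5:6] <- FALSE
    expect_equal(fillHoles(m), oracleFillHoles(m))
    expect_true(all(m[fillHoles(m) == FALSE] == FALSE))  # extensive
  }
})

test_that("sizeFilter keeps components with areas inside the bounds", {
  m <- matrix(FALSE, 60, 60)
  m[2, 2:4] <- TRUE                                  # area 3
  m[10:14, 10:19] <- TRUE                            # area 50
  m[25:54, 25:54] <- TRUE                            # area 900
  kept <- sizeFilter(m, 10, 500)
  expect_equal(sum(kept), 50)
  expect_equal(sizeFilter(m, 0, Inf), m)             # identity bounds
  expect_error(sizeFilter(m, 10, 5), "minArea")
  set.seed(6)
  speckle <- matrix(runif(4096) < 0.3, 64, 64)
  expect_equal(sizeFilter(speckle, 5, 100),
               oracleSizeFilter(speckle, 5, 100))
  # surviving components re-measure within bounds
  lm <- labelMask(sizeFilter(speckle, 5, 100))
  if (nLabels(lm) > 0) {
    areas <- tabulate(labelData(lm)[labelData(lm) > 0], nLabels(lm))
    expect_true(all(areas >= 5 & areas <= 100))
  }
})

test_that("erosion matches the neighborhood-AND oracle and its geometry", {
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_equal(sum(erodeMask(single, 1)), 0)         # single pixel vanishes
  sq <- matrix(FALSE, 40, 40); sq[8:32, 8:32] <- TRUE
  e10 <- erodeMask(sq, 10)
  expected <- matrix(FALSE, 40, 40); expected[18:22, 18:22] <- TRUE
  expect_equal(e10, expected)                        # 25-px -> centred 5-px
  m <- randomBlobMask(9, 48)
  expect_identical(erodeMask(m, 0), m)               # 0 cycles = identity
  expect_equal(erodeMask(m, 2), oracleErode(m, 2))
  expect_equal(erodeMask(m, 1, "cross"), oracleErode(m, 1, diamond = TRUE))
  # anti-extensive and monotone in cycles
  e1 <- erodeMask(m, 1); e2 <- erodeMask(m, 2)
  expect_true(all(!e1 | m))
  expect_true(all(!e2 | e1))
  expect_error(erodeMask(m, -1), "cycles")
})

test_that("mask difference behaves as set difference", {
  a <- randomBlobMask(12, 32)
  expect_equal(sum(maskDifference(a, a)), 0)
  empty <- matrix(FALSE, 32, 32)
  expect_equal(maskDifference(a, empty), a)
  d <- disk(41, 15)
  er <- erodeMask(d, 10)
  ring <- maskDifference(d, er)
  expect_equal(sum(ring), sum(d) - sum(er))          # area bookkeeping
  expect_error(maskDifference(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("meanIntensity averages over the mask", {
  pl <- matrix(7, 5, 5)
  expect_equal(meanIntensity(pl, matrix(TRUE, 5, 5)), 7)
  pl2 <- matrix(1:4, 2, 2)
  mk <- matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2)
  expect_equal(meanIntensity(pl2, mk), 3)            # mean of {2, 4}
  set.seed(13)
  pl3 <- matrix(runif(100), 10, 10)
  mk3 <- matrix(runif(100) < 0.4, 10, 10)
  acc <- 0; n <- 0
  for (i in 1:10) for (j in 1:10) if (mk3[i, j]) {
    acc <- acc + pl3[i, j]; n <- n + 1
  }
  expect_equal(meanIntensity(pl3, mk3), acc / n)
  expect_error(meanIntensity(pl3, matrix(FALSE, 10, 10)), "empty")
})

test_that("labelMask produces valid, connected, deterministic labels", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE; m[7:8, 7:9] <- TRUE; m[5, 5] <- TRUE
  lm <- labelMask(m)
  expect_equal(nLabels(lm), 3)
  expect_true(validObject(lm))
  # row-major order of first pixels: (2,2) then (5,5) then (7,7)
  expect_equal(labelData(lm)[2, 2], 1L)
  expect_equal(labelData(lm)[5, 5], 2L)
  expect_equal(labelData(lm)[7, 7], 3L)
  # diagonal touch merges under 8- but not 4-connectivity
  dg <- matrix(FALSE, 4, 4); dg[1, 1] <- TRUE; dg[2, 2] <- TRUE
  expect_equal(nLabels(labelMask(dg, 8)), 1)
  expect_equal(nLabels(labelMask(dg, 4)), 2)
})
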