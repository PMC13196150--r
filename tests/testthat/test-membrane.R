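brightDisk <- function(n = 120, r = 40, fg = 100, bg = 5) {
  img <- matrix(bg, n, n)
  d <- outer(1:n, 1:n, function(y, x)
    (y - n / 2)^2 + (x - n / 2)^2 <= r^2)
  img[d] <- fg
  list(img = img, mask = d)
}

test_that("whole-cell segmentation recovers a bright disk", {
  b <- brightDisk()
  cells <- wholeCellMask(b$img)
  expect_equal(nLabels(cells), 1)
  got <- labelData(cells) > 0
  expect_gte(sum(got & b$mask) / sum(b$mask), 0.95)
})

test_that("background-only images give an empty result, not an error", {
  expect_equal(nLabels(wholeCellMask(matrix(5, 64, 64))), 0)
  # debris-sized specks only: everything falls below the size bounds
  img <- matrix(5, 64, 64)
  img[10:12, 10:12] <- 100
  img[40:42, 50:52] <- 100
  expect_equal(nLabels(wholeCellMask(img, sizeBounds = c(500, Inf))), 0)
  expect_length(quantifyMembrane(img, sizeBounds = c(500, Inf)), 0)
})

test_that("size bounds select cells; each component is its own record", {
  img <- matrix(5, 140, 140)
  big <- outer(1:140, 1:140, function(y, x) (y - 45)^2 + (x - 45)^2 <= 35^2)
  small <- outer(1:140, 1:140, function(y, x)
    (y - 110)^2 + (x - 110)^2 <= 9^2)
  img[big] <- 100; img[small] <- 100
  expect_equal(nLabels(wholeCellMask(img, sizeBounds = c(500, Inf))), 1)
  res <- quantifyMembrane(img, sizeBounds = c(100, Inf), erodeCycles = 3)
  expect_length(res, 2)
  expect_equal(vapply(res, function(r) r@cellId, integer(1)), 1:2)
})

test_that("membrane quantification recovers the ring/cell intensity ratio", {
  ests <- numeric()
  for (ratio in c(1, 2, 4)) {
    sim <- simulateConfocalCell(list(membraneRatio = ratio), seed = 11)
    tr <- sim$truth
    truth <- meanIntensity(tr@rasters$noiselessProjection,
                           tr@rasters$ringMask) /
             meanIntensity(tr@rasters$noiselessProjection,
                           tr@rasters$cellMask)
    res <- quantifyMembrane(sim$stack)
    expect_length(res, 1)
    est <- res[[1]]@relativeMembraneIntensity
    expect_lt(abs(est / truth - 1), 0.1)
    # exact area conservation
    expect_identical(sum(res[[1]]@wholeCellMask),
                     sum(res[[1]]@cytosolMask) + sum(res[[1]]@membraneMask))
    # weighted-mean property
    expect_true(res[[1]]@meanWhole >= min(res[[1]]@meanCytosol,
                                          res[[1]]@meanMembrane))
    expect_true(res[[1]]@meanWhole <= max(res[[1]]@meanCytosol,
                                          res[[1]]@meanMembrane))
    ests <- c(ests, est)
  }
  expect_true(all(diff(ests) > 0))        # monotone in the true ratio
})

test_that("a uniform-intensity cell has relative membrane intensity ~1", {
  sim <- simulateConfocalCell(list(membraneRatio = 1), seed = 3)
  res <- quantifyMembrane(sim$stack)[[1]]
  expect_lt(abs(res@relativeMembraneIntensity - 1), 0.02)
})

test_that("over-erosion of a small cell raises a degenerate-cell error", {
  img <- matrix(5, 60, 60)
  tiny <- outer(1:60, 1:60, function(y, x)
    (y - 30)^2 + (x - 30)^2 <= 7.5^2)                # diameter 15 px
  img[tiny] <- 100
  expect_error(quantifyMembrane(img, sizeBounds = c(50, Inf),
                                erodeCycles = 10L),
               "degenerate cell 1")
})

test_that("membraneTable flattens results for CSV export", {
  sim <- simulateConfocalCell(list(), seed = 4)
  tab <- membraneTable(quantifyMembrane(sim$stack), image = "cell.tif")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$areaWhole, tab$areaCytosol + tab$areaMembrane)
  expect_equal(tab$relativeMembraneIntensity,
               tab$meanMembrane / tab$meanWhole)
})
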