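# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

mergeParams <- function(defaults, params) {
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(params)] <- params
  defaults
}

# Add a 2D Gaussian spot (0-based centre) to an image, truncated at 4 sigma.
addSpot <- function(img, y0, x0, amplitude, sigma) {
  r <- ceiling(4 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  ys <- max(0, floor(y0 - r)):min(nr - 1, ceiling(y0 + r))
  xs <- max(0, floor(x0 - r)):min(nc - 1, ceiling(x0 + r))
  if (!length(ys) || !length(xs)) return(img)
  g <- amplitude * exp(-(outer((ys - y0)^2, (xs - x0)^2, "+")) /
                         (2 * sigma^2))
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + g
  img
}

inEllipse <- function(y, x, cy, cx, ry, rx) {
  ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1
}

applyCameraNoise <- function(img, poisson, readNoiseSd) {
  if (poisson)
    img <- matrix(rpois(length(img), lambda = img), nrow(img), ncol(img))
  if (readNoiseSd > 0)
    img <- img + matrix(rnorm(length(img), sd = readNoiseSd),
                        nrow(img), ncol(img))
  round(pmax(img, 0))
}

#' Simulate a two-channel TIRF time series with known colocalization
#'
#' Emulates TIRF movies of vesicles at the plasma membrane: reference-channel
#' spots are placed uniformly inside an elliptical cell footprint and diffuse
#' with Brownian steps; a fraction \code{colocFraction} of query-channel
#' spots ride on reference spots (offset by \code{jitterSigmaPx}); the
#' remaining query spots are kept at least \code{3 * psfSigma} pixels from
#' every reference spot at every frame by rejection sampling, so the
#' ground-truth flag stays meaningful as vesicles move. Spots are rendered
#' as 2D Gaussians on top of a diffuse cytosolic pool filling the cell
#' footprint (\code{cellBackground}, present in both channels; this is what
#' makes the cell footprint segmentable at all). Poisson shot noise is
#' applied to the expected signal and Gaussian read noise added. Identical
#' parameters and seed give bit-identical output.
#'
#' @param params named list overriding the defaults: \code{width, height}
#'   (256 px), \code{nFrames} (20), \code{nReference, nQuery} (100 each),
#'   \code{colocFraction} (0.5), \code{psfSigma} (1.5 px),
#'   \code{jitterSigmaPx} (0.5), \code{stepSigmaUm} (0.05 um/frame Brownian
#'   step), \code{background} (100 camera counts outside the cell),
#'   \code{cellBackground} (80 diffuse counts added inside the cell
#'   footprint), \code{amplitude} (600),
#'   \code{readNoiseSd} (10), \code{poissonNoise} (TRUE),
#'   \code{pixelSizeUm} (0.1), \code{frameIntervalS} (10, i.e. 1 frame/10 s),
#'   \code{cellRadiiFrac} (0.35 of height, 0.42 of width).
#' @param seed RNG seed.
#' @return list with \code{stack} (an \linkS4class{ImageStack} with axes
#'   time, channel, y, x; channel 1 = query, channel 2 = reference) and
#'   \code{truth} (a \linkS4class{GroundTruth} whose \code{records} hold the
#'   true per-frame spot positions and colocalization flags).
#' @export
simulateTirfSeries <- function(params = list(), seed = 1L) {
  p <- mergeParams(list(
    width = 256L, height = 256L, nFrames = 20L,
    nReference = 100L, nQuery = 100L, colocFraction = 0.5,
    psfSigma = 1.5, jitterSigmaPx = 0.5, stepSigmaUm = 0.05,
    background = 100, cellBackground = 80, amplitude = 600, readNoiseSd = 10,
    poissonNoise = TRUE, pixelSizeUm = 0.1, frameIntervalS = 10,
    cellRadiiFrac = c(0.35, 0.42)), params)
  if (!(p$colocFraction >= 0 && p$colocFraction <= 1))
    stop("colocFraction must lie in [0, 1]", call. = FALSE)
  if (p$nReference < 0 || p$nQuery < 0)
    stop("spot counts must be >= 0", call. = FALSE)
  cy <- (p$height - 1) / 2; cx <- (p$width - 1) / 2
  ry <- p$cellRadiiFrac[1] * p$height
  rx <- p$cellRadiiFrac[2] * p$width
  margin <- 3 * p$psfSigma + 2
  sep <- 3 * p$psfSigma
  stepPx <- p$stepSigmaUm / p$pixelSizeUm
  nColoc <- round(p$colocFraction * p$nQuery)

  withSeed(seed, {
    drawInCell <- function(n) {
      ys <- numeric(n); xs <- numeric(n); got <- 0L
      while (got < n) {
        y <- runif(1, cy - ry, cy + ry); x <- runif(1, cx - rx, cx + rx)
        if (inEllipse(y, x, cy, cx, ry - margin, rx - margin)) {
          got <- got + 1L; ys[got] <- y; xs[got] <- x
        }
      }
      cbind(ys, xs)
    }
    refPos <- if (p$nReference > 0) drawInCell(p$nReference) else
      matrix(numeric(), 0, 2)
    farFromRefs <- function(y, x)
      p$nReference == 0 ||
        min((refPos[, 1] - y)^2 + (refPos[, 2] - x)^2) >= sep^2
    drawFree <- function() {
      repeat {
        q <- drawInCell(1)
        if (farFromRefs(q[1], q[2])) return(q)
      }
    }
    attach <- if (nColoc > 0) sample.int(max(p$nReference, 1), nColoc,
                                         replace = nColoc > p$nReference)
              else integer()
    freePos <- if (p$nQuery - nColoc > 0)
      do.call(rbind, replicate(p$nQuery - nColoc, drawFree(),
                               simplify = FALSE))
    else matrix(numeric(), 0, 2)

    cellMask <- outer(seq_len(p$height) - 1, seq_len(p$width) - 1,
                      function(y, x) inEllipse(y, x, cy, cx, ry, rx))
    baseImg <- p$background + p$cellBackground * cellMask
    arr <- array(0, dim = c(p$nFrames, 2L, p$height, p$width))
    records <- vector("list", p$nFrames)
    for (t in seq_len(p$nFrames)) {
      if (t > 1 && p$nReference > 0) {
        for (i in seq_len(p$nReference)) {
          for (try in 1:100) {
            ny <- refPos[i, 1] + rnorm(1, sd = stepPx)
            nx <- refPos[i, 2] + rnorm(1, sd = stepPx)
            if (inEllipse(ny, nx, cy, cx, ry - margin, rx - margin)) {
              refPos[i, ] <- c(ny, nx); break
            }
          }
        }
        if (nrow(freePos)) {
          for (i in seq_len(nrow(freePos))) {
            ok <- FALSE
            for (try in 1:100) {
              ny <- freePos[i, 1] + rnorm(1, sd = stepPx)
              nx <- freePos[i, 2] + rnorm(1, sd = stepPx)
              if (inEllipse(ny, nx, cy, cx, ry - margin, rx - margin) &&
                  farFromRefs(ny, nx)) {
                freePos[i, ] <- c(ny, nx); ok <- TRUE; break
              }
            }
            if (!ok) freePos[i, ] <- drawFree()   # ref drifted onto the spot
          }
        }
      }
      qPos <- matrix(numeric(), 0, 2)
      if (nColoc > 0) {
        jit <- matrix(rnorm(2 * nColoc, sd = p$jitterSigmaPx), ncol = 2)
        qPos <- refPos[attach, , drop = FALSE] + jit
      }
      qPos <- rbind(qPos, freePos)

      qImg <- baseImg
      rImg <- baseImg
      if (nrow(qPos)) for (i in seq_len(nrow(qPos)))
        qImg <- addSpot(qImg, qPos[i, 1], qPos[i, 2], p$amplitude, p$psfSigma)
      if (p$nReference > 0) for (i in seq_len(p$nReference))
        rImg <- addSpot(rImg, refPos[i, 1], refPos[i, 2], p$amplitude,
                        p$psfSigma)
      arr[t, 1, , ] <- applyCameraNoise(qImg, p$poissonNoise, p$readNoiseSd)
      arr[t, 2, , ] <- applyCameraNoise(rImg, p$poissonNoise, p$readNoiseSd)

      recQ <- if (nrow(qPos))
        data.frame(frame = t - 1L, channel = "query",
                   id = seq_len(nrow(qPos)), y = qPos[, 1], x = qPos[, 2],
                   colocalized = c(rep(TRUE, nColoc),
                                   rep(FALSE, nrow(freePos))))
      else NULL
      recR <- if (p$nReference > 0)
        data.frame(frame = t - 1L, channel = "reference",
                   id = seq_len(p$nReference), y = refPos[, 1],
                   x = refPos[, 2], colocalized = NA)
      else NULL
      records[[t]] <- rbind(recQ, recR)
    }
    stack <- ImageStack(arr, c("time", "channel", "y", "x"),
                        pixelSizeUm = p$pixelSizeUm,
                        frameIntervalS = p$frameIntervalS)
    truth <- new("GroundTruth", type = "tirf",
                 records = do.call(rbind, records), params = p,
                 rasters = list(cellMask = cellMask), seed = as.integer(seed))
    list(stack = stack, truth = truth)
  })
}

#' Simulate a confocal z-stack of a cell with a membrane ring
#'
#' An elliptical cell with uniform cytosol intensity and a peripheral ring of
#' \code{ringWidth} pixels at \code{membraneRatio} times the cytosol
#' intensity, over a constant camera background, modulated along z by a
#' Gaussian focal envelope; Poisson shot noise plus Gaussian read noise.
#' The noiseless stack, its sum projection, and the true cell/ring masks are
#' stored in the ground truth for direct comparison.
#'
#' @param params named list overriding the defaults: \code{width, height}
#'   (192 px), \code{nz} (5), \code{cellRadiiFrac} (0.35, 0.40),
#'   \code{ringWidth} (12 px), \code{membraneRatio} (2),
#'   \code{cytosolIntensity} (300), \code{background} (20),
#'   \code{readNoiseSd} (5), \code{poissonNoise} (TRUE),
#'   \code{pixelSizeUm} (0.1).
#' @param seed RNG seed.
#' @return list with \code{stack} (axes z, y, x) and \code{truth} (rasters:
#'   \code{noiselessStack}, \code{noiselessProjection}, \code{cellMask},
#'   \code{ringMask}, \code{innerMask}).
#' @export
simulateConfocalCell <- function(params = list(), seed = 1L) {
  p <- mergeParams(list(
    width = 192L, height = 192L, nz = 5L, cellRadiiFrac = c(0.35, 0.40),
    ringWidth = 12, membraneRatio = 2, cytosolIntensity = 300,
    background = 20, readNoiseSd = 5, poissonNoise = TRUE,
    pixelSizeUm = 0.1), params)
  if (p$membraneRatio <= 0) stop("membraneRatio must be > 0", call. = FALSE)
  cy <- (p$height - 1) / 2; cx <- (p$width - 1) / 2
  ry <- p$cellRadiiFrac[1] * p$height
  rx <- p$cellRadiiFrac[2] * p$width
  if (p$ringWidth < 1) stop("ringWidth must be >= 1 px", call. = FALSE)
  if (p$ringWidth >= min(ry, rx))
    stop("ring wider than the cell radius", call. = FALSE)
  ygrid <- seq_len(p$height) - 1; xgrid <- seq_len(p$width) - 1
  cellMask <- outer(ygrid, xgrid, function(y, x)
    inEllipse(y, x, cy, cx, ry, rx))
  innerMask <- outer(ygrid, xgrid, function(y, x)
    inEllipse(y, x, cy, cx, ry - p$ringWidth, rx - p$ringWidth))
  ringMask <- cellMask & !innerMask
  plane <- matrix(p$background, p$height, p$width)
  plane[cellMask] <- p$background + p$cytosolIntensity
  plane[ringMask] <- p$background + p$membraneRatio * p$cytosolIntensity
  zc <- (p$nz + 1) / 2
  env <- exp(-0.5 * ((seq_len(p$nz) - zc) / (p$nz / 3))^2)
  noiseless <- array(0, dim = c(p$nz, p$height, p$width))
  for (z in seq_len(p$nz))
    noiseless[z, , ] <- p$background + env[z] * (plane - p$background)
  withSeed(seed, {
    arr <- array(0, dim = dim(noiseless))
    for (z in seq_len(p$nz))
      arr[z, , ] <- applyCameraNoise(noiseless[z, , ], p$poissonNoise,
                                     p$readNoiseSd)
    stack <- ImageStack(arr, c("z", "y", "x"), pixelSizeUm = p$pixelSizeUm)
    truth <- new("GroundTruth", type = "confocal_cell",
                 records = data.frame(), params = p,
                 rasters = list(noiselessStack = noiseless,
                                noiselessProjection = apply(noiseless, c(2, 3),
                                                            sum),
                                cellMask = cellMask, ringMask = ringMask,
                                innerMask = innerMask),
                 seed = as.integer(seed))
    list(stack = stack, truth = truth)
  })
}

#' Simulate a cohort of stationary and dynamic trajectories
#'
#' Tracks start on a wide grid (so nearest-neighbour linking is unambiguous)
#' and are shuffled across grid sites. Stationary tracks jitter around their
#' anchor; dynamic tracks advance along a random direction. Each track's net
#' first-to-last displacement is drawn uniformly in
#' \code{(0, 0.8) * thresholdUm} (stationary) or
#' \code{(1.2, 5) * thresholdUm} (dynamic) and imposed exactly by a linear
#' correction of the path, so the downstream taxonomy is checkable against
#' exact truth. Detections are emitted per frame in shuffled order without
#' identities; linking has to recover them.
#'
#' @param nStationary,nDynamic cohort sizes.
#' @param thresholdUm displacement threshold the cohort straddles (0.67 um).
#' @param seed RNG seed.
#' @param params named list overriding: \code{nFrames} (30),
#'   \code{frameIntervalS} (1 s), \code{pixelSizeUm} (0.1),
#'   \code{gridSpacingUm} (8), \code{jitterSigmaUm} (0.02).
#' @return list with \code{detections} (data.frame frame, y, x in 0-based
#'   pixels) and \code{truth} (records: trackId, motionClass,
#'   displacementUm; full true points under \code{rasters$points}).
#' @export
simulateTracks <- function(nStationary = 320L, nDynamic = 109L,
                           thresholdUm = 0.67, seed = 1L, params = list()) {
  stopifnot(nStationary >= 0, nDynamic >= 0, thresholdUm > 0)
  p <- mergeParams(list(nFrames = 30L, frameIntervalS = 1,
                        pixelSizeUm = 0.1, gridSpacingUm = 8,
                        jitterSigmaUm = 0.02), params)
  n <- nStationary + nDynamic
  emptyDet <- data.frame(frame = integer(), y = numeric(), x = numeric())
  if (n == 0)
    return(list(detections = emptyDet,
                truth = new("GroundTruth", type = "tracks",
                            records = data.frame(), params = p,
                            rasters = list(points = emptyDet),
                            seed = as.integer(seed))))
  withSeed(seed, {
    side <- ceiling(sqrt(n))
    spacingPx <- p$gridSpacingUm / p$pixelSizeUm
    starts <- (expand.grid(gy = seq_len(side), gx = seq_len(side)) - 1) *
      spacingPx + 10
    starts <- starts[seq_len(n), ]
    cls <- sample(c(rep("stationary", nStationary),
                    rep("dynamic", nDynamic)))
    disp <- ifelse(cls == "stationary",
                   runif(n, 0, 0.8) * thresholdUm,
                   runif(n, 1.2, 5) * thresholdUm)
    theta <- runif(n, 0, 2 * pi)
    nf <- p$nFrames
    jitPx <- p$jitterSigmaUm / p$pixelSizeUm
    pts <- vector("list", n)
    for (i in seq_len(n)) {
      dy <- cumsum(c(0, rnorm(nf - 1, sd = jitPx)))
      dx <- cumsum(c(0, rnorm(nf - 1, sd = jitPx)))
      if (cls[i] == "dynamic") {
        prog <- (seq_len(nf) - 1) / (nf - 1)
        dy <- dy + prog * disp[i] / p$pixelSizeUm * sin(theta[i])
        dx <- dx + prog * disp[i] / p$pixelSizeUm * cos(theta[i])
      }
      # impose the exact net displacement
      targetY <- disp[i] / p$pixelSizeUm * sin(theta[i])
      targetX <- disp[i] / p$pixelSizeUm * cos(theta[i])
      prog <- (seq_len(nf) - 1) / (nf - 1)
      dy <- dy + prog * (targetY - dy[nf])
      dx <- dx + prog * (targetX - dx[nf])
      pts[[i]] <- data.frame(trackId = i, frame = seq_len(nf) - 1L,
                             y = starts$gy[i] + dy, x = starts$gx[i] + dx)
    }
    allPts <- do.call(rbind, pts)
    detections <- do.call(rbind, lapply(0:(nf - 1), function(f) {
      d <- allPts[allPts$frame == f, c("frame", "y", "x")]
      d[sample.int(nrow(d)), , drop = FALSE]
    }))
    rownames(detections) <- NULL
    truth <- new("GroundTruth", type = "tracks",
                 records = data.frame(trackId = seq_len(n),
                                      motionClass = cls,
                                      displacementUm = disp),
                 params = c(p, list(thresholdUm = thresholdUm)),
                 rasters = list(points = allPts), seed = as.integer(seed))
    list(detections = detections, truth = truth)
  })
}
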