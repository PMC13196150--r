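#' Configuration for TIRF vesicle colocalization analysis
#'
#' Defaults follow the published procedure where it states values (median
#' radius 4; cut-offs 0.5 and 0.01) and use documented package defaults
#' elsewhere (DoG sigmas 1 and 4 px; seed/outline sigmas 1 and 1.5 px).
#'
#' @param medianRadius reference-channel median pre-filter radius, pixels.
#' @param dogSigmas length-2 numeric, DoG small/large sigmas in pixels.
#' @param spotSigma,outlineSigma Voronoi-Otsu labeling sigmas in pixels.
#' @param cutHigh,cutLow overlap-score cut-offs; scores >= \code{cutHigh} are
#'   colocalized, scores < \code{cutLow} non-colocalized, the rest partial.
#' @param reciprocal also label reference-channel vesicles and score them
#'   against the query-channel mask (endosome-centric counts).
#' @param queryChannel,referenceChannel 1-based channel indices of the cargo
#'   (query) and endosome-marker (reference) channels.
#' @param maskStrategy cell-mask source: \code{"external"}/\code{"manual"}
#'   (per-frame masks supplied by the caller, e.g. from a trained segmenter)
#'   or \code{"threshold_fallback"} (intensity-based, see
#'   \code{\link{cellMaskForFrame}}).
#' @return A \linkS4class{ColocConfig}.
#' @export
colocConfig <- function(medianRadius = 4L, dogSigmas = c(1, 4),
                        spotSigma = 1, outlineSigma = 1.5,
                        cutHigh = 0.5, cutLow = 0.01, reciprocal = FALSE,
                        queryChannel = 1L, referenceChannel = 2L,
                        maskStrategy = "threshold_fallback") {
  new("ColocConfig", medianRadius = as.integer(medianRadius),
      dogSigmas = as.numeric(dogSigmas), spotSigma = spotSigma,
      outlineSigma = outlineSigma, cutHigh = cutHigh, cutLow = cutLow,
      reciprocal = reciprocal, queryChannel = as.integer(queryChannel),
      referenceChannel = as.integer(referenceChannel),
      maskStrategy = maskStrategy)
}

setMethod("show", "ColocConfig", function(object) {
  cat(sprintf(paste0("ColocConfig: median r=%d, DoG (%g, %g), spot/outline ",
                     "(%g, %g), cuts [%g, %g], query ch %d vs reference ch ",
                     "%d, masks '%s'%s\n"),
              object@medianRadius, object@dogSigmas[1], object@dogSigmas[2],
              object@spotSigma, object@outlineSigma, object@cutLow,
              object@cutHigh, object@queryChannel, object@referenceChannel,
              object@maskStrategy,
              if (object@reciprocal) ", reciprocal" else ""))
})

#' Voronoi-Otsu labeling of diffraction-limited spots
#'
#' Spot segmentation for non-negative enhancement maps (typically DoG
#' output): (1) blur with \code{spotSigma} and take local maxima
#' (8-neighborhood; an equal-value plateau contributes one seed at its
#' row-major-first pixel) as seeds; (2) blur with \code{outlineSigma} and
#' binarize with an Otsu threshold to get the foreground; (3) drop seeds
#' outside the foreground; (4) partition the foreground among the surviving
#' seeds by expanding each seed over 8-connected foreground in order of
#' Euclidean distance to the seed (ties to the lower label). Foreground
#' components without a seed stay background. A constant plane yields an
#' empty label map.
#'
#' @param plane non-negative numeric matrix.
#' @param spotSigma,outlineSigma Gaussian sigmas in pixels.
#' @return A \linkS4class{LabelMap}.
#' @export
voronoiOtsuLabel <- function(plane, spotSigma = 1, outlineSigma = 1.5) {
  stopifnot(is.matrix(plane), is.numeric(plane))
  if (any(plane < 0)) stop("plane must be non-negative", call. = FALSE)
  empty <- function() new("LabelMap",
                          data = matrix(0L, nrow(plane), ncol(plane)),
                          nLabels = 0L)
  if (max(plane) <= min(plane)) return(empty())
  seedImg <- gaussianBlur(plane, spotSigma)
  outlineImg <- gaussianBlur(plane, outlineSigma)
  if (max(outlineImg) <= min(outlineImg)) return(empty())
  fg <- applyThreshold(outlineImg, autoThreshold(outlineImg, "otsu"))
  if (!any(fg)) return(empty())
  seeds <- cpp_local_maxima(seedImg) & fg
  if (!any(seeds)) return(empty())
  # deterministic labels: row-major order of seed pixels
  ord <- order(row(seeds)[seeds], col(seeds)[seeds])
  seedLab <- matrix(0L, nrow(plane), ncol(plane))
  seedLab[seeds] <- order(ord)
  lab <- cpp_seed_grow(seedLab, fg)
  # compact labels (all seeds survive, but guard against empty ones)
  u <- sort(unique(lab[lab > 0]))
  if (length(u) && !identical(u, seq_along(u)))
    lab <- matrix(match(lab, u, nomatch = 0L), nrow(lab), ncol(lab))
  new("LabelMap", data = lab, nLabels = length(u))
}

#' Cell mask for one TIRF frame
#'
#' External and manual masks are validated and passed through. The
#' intensity-based fallback median-filters the reference plane, applies a
#' triangle threshold, fills holes and keeps the largest component; it is a
#' stand-in for a trained cell segmenter and is adequate for a single bright
#' cell on a dark background.
#'
#' @param referencePlane numeric matrix (reference channel of the frame).
#' @param strategy \code{"external"}, \code{"threshold_fallback"} or
#'   \code{"manual"}.
#' @param externalMask logical matrix for the external/manual strategies.
#' @param medianRadius fallback pre-filter radius in pixels.
#' @return Logical cell mask.
#' @export
cellMaskForFrame <- function(referencePlane,
                             strategy = c("threshold_fallback", "external",
                                          "manual"),
                             externalMask = NULL, medianRadius = 4L) {
  strategy <- match.arg(strategy)
  if (strategy %in% c("external", "manual")) {
    if (is.null(externalMask))
      stop("strategy '", strategy, "' requires an external mask",
           call. = FALSE)
    assertMask(externalMask, "externalMask")
    if (!identical(dim(externalMask), dim(referencePlane)))
      stop("external mask shape does not match the frame", call. = FALSE)
    return(externalMask)
  }
  filtered <- diskMedianFilter(referencePlane, medianRadius)
  if (max(filtered) <= min(filtered))
    return(matrix(FALSE, nrow(referencePlane), ncol(referencePlane)))
  mask <- applyThreshold(filtered, autoThreshold(filtered, "triangle"))
  mask <- fillHoles(mask)
  largestComponent(mask)
}

#' Overlap scores of labeled vesicles against a reference mask
#'
#' For each label with pixel set P the score is \eqn{|P \cap ref| / |P|}:
#' the mean of the binary reference over the label, 1 meaning the vesicle is
#' fully covered by the reference mask.
#'
#' @param labels a \linkS4class{LabelMap} of vesicles.
#' @param referenceMask logical matrix of the same shape.
#' @return data.frame with \code{vesicleId}, \code{area} (pixels),
#'   \code{centroidY}, \code{centroidX} (0-based pixels) and \code{score}.
#' @export
overlapScores <- function(labels, referenceMask) {
  stopifnot(is(labels, "LabelMap"))
  assertMask(referenceMask, "referenceMask")
  if (!identical(dim(labels@data), dim(referenceMask)))
    stop("label map and reference mask shapes differ", call. = FALSE)
  n <- labels@nLabels
  if (n == 0)
    return(data.frame(vesicleId = integer(), area = integer(),
                      centroidY = numeric(), centroidX = numeric(),
                      score = numeric()))
  lab <- labels@data
  inside <- lab > 0
  idx <- lab[inside]
  area <- tabulate(idx, nbins = n)
  hit <- tabulate(idx[referenceMask[inside]], nbins = n)
  cy <- rowsum(as.numeric(row(lab)[inside]) - 1, idx)[, 1] / area
  cx <- rowsum(as.numeric(col(lab)[inside]) - 1, idx)[, 1] / area
  data.frame(vesicleId = seq_len(n), area = area,
             centroidY = as.numeric(cy), centroidX = as.numeric(cx),
             score = hit / area)
}

#' Classify an overlap score
#'
#' Scores of at least \code{cutHigh} are \code{colocalized}; scores below
#' \code{cutLow} are \code{non}; the rest are \code{partial}. The boundary
#' policy makes the three classes partition [0, 1]: a score of exactly
#' \code{cutHigh} (0.5) is colocalized and scores in (0, \code{cutLow}) are
#' non-colocalized.
#'
#' @param score numeric vector of scores in [0, 1].
#' @param config a \linkS4class{ColocConfig} (cut-offs 0.5 / 0.01 by default).
#' @return factor with levels \code{colocalized}, \code{partial}, \code{non}.
#' @examples
#' classifyOverlap(c(0, 0.3, 0.75))
#' @export
classifyOverlap <- function(score, config = colocConfig()) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  cls <- ifelse(score >= config@cutHigh, "colocalized",
                ifelse(score >= config@cutLow, "partial", "non"))
  factor(cls, levels = c("colocalized", "partial", "non"))
}

# One analysis direction for one frame: label DoG(queryPlane)*cellMask spots,
# score against the triangle-threshold vesicle mask of DoG(refPlane).
scoreDirection <- function(queryPlane, refPlane, cellMask, config) {
  dogQ <- dogFilter(queryPlane, config@dogSigmas[1], config@dogSigmas[2])
  dogQ <- dogQ * cellMask
  labels <- voronoiOtsuLabel(dogQ, config@spotSigma, config@outlineSigma)
  dogR <- dogFilter(refPlane, config@dogSigmas[1], config@dogSigmas[2])
  refMask <- if (max(dogR) > min(dogR)) {
    applyThreshold(dogR, autoThreshold(dogR, "triangle")) & cellMask
  } else matrix(FALSE, nrow(refPlane), ncol(refPlane))
  recs <- overlapScores(labels, refMask)
  recs$colocClass <- classifyOverlap(recs$score, config)
  recs
}

summarizeClasses <- function(cls) {
  tab <- table(cls)
  n <- length(cls)
  c(nTotal = n,
    nColoc = as.integer(tab["colocalized"]),
    nPartial = as.integer(tab["partial"]),
    nNon = as.integer(tab["non"]),
    colocRatio = if (n > 0) as.numeric(tab["colocalized"]) / n else NA_real_)
}

#' Analyze a two-channel TIRF time series for vesicle colocalization
#'
#' For every frame: a cell mask is obtained (external masks or the intensity
#' fallback on the median-filtered reference channel); query-channel vesicles
#' are enhanced with a DoG filter, restricted to the cell mask and segmented
#' by \code{\link{voronoiOtsuLabel}}; the reference channel is DoG-filtered
#' and triangle-thresholded (restricted to the cell) to a binary vesicle
#' mask; each query vesicle's overlap score against that mask is classified
#' (colocalized / partial / non) and summarized as the colocalization ratio
#' \code{nColoc / nTotal}. Mean raw intensity of both channels within the
#' cell mask is reported per frame. Frames with an empty cell mask are
#' skipped with a warning. With \code{config@reciprocal}, the
#' reference-channel vesicles are additionally labeled and scored against the
#' query-channel triangle mask, yielding query-positive and query-negative
#' reference-vesicle counts and their ratio (positive : zero-overlap;
#' partially overlapping vesicles are counted but excluded from the ratio).
#'
#' @param stack an \linkS4class{ImageStack} with axes time, channel, y, x
#'   (exactly 2 channels).
#' @param config a \linkS4class{ColocConfig}.
#' @param masks optional per-frame cell masks: a logical array (time, y, x)
#'   or a list of logical matrices, required for the external/manual
#'   strategies.
#' @return A list with \code{vesicles} (one row per detected query vesicle:
#'   frame, id, area, centroid, score, class), \code{frames} (per-frame
#'   summary incl. counts, ratio and channel means), \code{reciprocal}
#'   (per-frame reference-vesicle counts, or NULL), and \code{skippedFrames}
#'   (0-based indices). Frames are 0-based throughout.
#' @export
analyzeTirfSeries <- function(stack, config = colocConfig(), masks = NULL) {
  stopifnot(is(stack, "ImageStack"))
  if (!all(c("time", "channel") %in% stackAxes(stack)))
    stop("stack must have time and channel axes", call. = FALSE)
  if (axisLength(stack, "channel") != 2)
    stop("exactly 2 channels are required", call. = FALSE)
  nt <- axisLength(stack, "time")
  getMask <- function(t) {
    if (is.null(masks)) return(NULL)
    m <- if (is.list(masks)) masks[[t]] else
      matrix(masks[t, , ], dim(masks)[2], dim(masks)[3])
    storage.mode(m) <- "logical"
    m
  }
  vesicles <- list(); frames <- list(); recip <- list()
  skipped <- integer()
  for (t in seq_len(nt)) {
    q <- getPlane(stack, time = t, channel = config@queryChannel)
    r <- getPlane(stack, time = t, channel = config@referenceChannel)
    ext <- getMask(t)
    if (config@maskStrategy %in% c("external", "manual") && is.null(ext))
      stop("missing external mask for frame ", t - 1, call. = FALSE)
    cellMask <- cellMaskForFrame(diskMedianFilter(r, config@medianRadius),
                                 strategy = config@maskStrategy,
                                 externalMask = ext, medianRadius = 0L)
    if (!any(cellMask)) {
      warning("frame ", t - 1, ": empty cell mask, skipped")
      skipped <- c(skipped, t - 1L)
      next
    }
    recs <- scoreDirection(q, r, cellMask, config)
    if (nrow(recs)) recs <- cbind(frame = t - 1L, recs)
    else recs <- cbind(frame = integer(), recs)
    vesicles[[length(vesicles) + 1]] <- recs
    s <- summarizeClasses(recs$colocClass)
    frames[[length(frames) + 1]] <- data.frame(
      frame = t - 1L, nTotal = s["nTotal"], nColoc = s["nColoc"],
      nPartial = s["nPartial"], nNon = s["nNon"],
      colocRatio = s["colocRatio"],
      meanIntensityQuery = meanIntensity(q, cellMask),
      meanIntensityReference = meanIntensity(r, cellMask),
      row.names = NULL)
    if (config@reciprocal) {
      rr <- scoreDirection(r, q, cellMask, config)
      sr <- summarizeClasses(rr$colocClass)
      recip[[length(recip) + 1]] <- data.frame(
        frame = t - 1L, nTotal = sr["nTotal"], nColoc = sr["nColoc"],
        nPartial = sr["nPartial"], nNon = sr["nNon"],
        posNegRatio = if (!is.na(sr["nNon"]) && sr["nNon"] > 0)
          sr["nColoc"] / sr["nNon"] else NA_real_,
        row.names = NULL)
    }
  }
  list(vesicles = do.call(rbind, vesicles),
       frames = do.call(rbind, frames),
       reciprocal = if (config@reciprocal) do.call(rbind, recip) else NULL,
       skippedFrames = skipped)
}
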