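#' Tracking configuration
#'
#' @param maxLinkDistanceUm maximum centroid displacement (micrometres)
#'   allowed when linking detections between frames.
#' @param maxFrameGap maximum number of frames a track may be bridged over
#'   (1 = consecutive frames only).
#' @param displacementThresholdUm net-displacement cut between stationary and
#'   dynamic tracks; 0.67 um by default. Tracks at exactly the threshold are
#'   stationary (the published taxonomy leaves equality unassigned).
#' @return A named list of validated parameters.
#' @export
trackingConfig <- function(maxLinkDistanceUm = 0.5, maxFrameGap = 1L,
                           displacementThresholdUm = 0.67) {
  stopifnot(maxLinkDistanceUm > 0, maxFrameGap >= 1,
            displacementThresholdUm > 0)
  list(maxLinkDistanceUm = maxLinkDistanceUm,
       maxFrameGap = as.integer(maxFrameGap),
       displacementThresholdUm = displacementThresholdUm)
}

#' Motion metrics of one trajectory
#'
#' @param points data.frame with columns \code{frame} (strictly increasing),
#'   \code{y}, \code{x} (0-based pixels).
#' @param pixelSizeUm,frameIntervalS physical calibration.
#' @return A one-row data.frame: \code{nPoints}, \code{displacementUm}
#'   (straight-line first-to-last), \code{pathLengthUm} (sum of steps),
#'   \code{meanSpeedUmS} (mean of per-step speeds; each step's time is the
#'   true elapsed time \code{frame gap * frameIntervalS}; \code{NA} for
#'   single-point tracks).
#' @export
trackMetrics <- function(points, pixelSizeUm, frameIntervalS) {
  stopifnot(nrow(points) >= 1, all(diff(points$frame) > 0))
  n <- nrow(points)
  if (n == 1)
    return(data.frame(nPoints = 1L, displacementUm = 0,
                      pathLengthUm = 0, meanSpeedUmS = NA_real_))
  dy <- diff(points$y); dx <- diff(points$x)
  stepUm <- sqrt(dy^2 + dx^2) * pixelSizeUm
  stepTime <- diff(points$frame) * frameIntervalS
  disp <- sqrt((points$y[n] - points$y[1])^2 +
               (points$x[n] - points$x[1])^2) * pixelSizeUm
  data.frame(nPoints = n, displacementUm = disp,
             pathLengthUm = sum(stepUm),
             meanSpeedUmS = mean(stepUm / stepTime))
}

#' Link per-frame detections into trajectories
#'
#' Greedy globally-nearest-first bipartite linking: for each frame, all
#' (active track, detection) pairs within \code{maxLinkDistanceUm} are sorted
#' by (distance, track id, detection index) and accepted greedily; unmatched
#' detections start new tracks; tracks may be bridged over gaps of up to
#' \code{maxFrameGap} frames. Deterministic, and invariant to the order of
#' detections within a frame up to exact distance ties.
#'
#' @param detections data.frame with columns \code{frame} (0-based integer),
#'   \code{y}, \code{x} (0-based pixels).
#' @param config see \code{\link{trackingConfig}}.
#' @param pixelSizeUm,frameIntervalS physical calibration used for link
#'   distances and the returned metrics.
#' @return A \linkS4class{TrackSet} with per-track metrics and motion classes
#'   already computed at \code{config$displacementThresholdUm}.
#' @export
linkDetections <- function(detections, config = trackingConfig(),
                           pixelSizeUm = 0.1, frameIntervalS = 10) {
  need <- c("frame", "y", "x")
  if (!all(need %in% names(detections)))
    stop("detections must have columns frame, y, x", call. = FALSE)
  pts <- detections[order(detections$frame), , drop = FALSE]
  tracks <- list()       # each: list(points = data.frame, lastFrame)
  if (nrow(pts)) {
    maxPx <- config$maxLinkDistanceUm / pixelSizeUm
    for (f in sort(unique(pts$frame))) {
      det <- pts[pts$frame == f, , drop = FALSE]
      nd <- nrow(det)
      active <- which(vapply(tracks, function(tr)
        tr$lastFrame < f & tr$lastFrame >= f - config$maxFrameGap,
        logical(1)))
      assigned <- rep(FALSE, nd)
      if (length(active) && nd) {
        last <- t(vapply(tracks[active], function(tr) {
          p <- tr$points
          c(p$y[nrow(p)], p$x[nrow(p)])
        }, numeric(2)))
        dmat <- sqrt(outer(last[, 1], det$y, "-")^2 +
                     outer(last[, 2], det$x, "-")^2)
        cand <- which(dmat <= maxPx, arr.ind = TRUE)
        if (nrow(cand)) {
          ord <- order(dmat[cand], active[cand[, 1]], cand[, 2])
          usedTrack <- rep(FALSE, length(active))
          for (i in ord) {
            ti <- cand[i, 1]; di <- cand[i, 2]
            if (usedTrack[ti] || assigned[di]) next
            usedTrack[ti] <- TRUE; assigned[di] <- TRUE
            k <- active[ti]
            tracks[[k]]$points <- rbind(tracks[[k]]$points,
                                        det[di, need, drop = FALSE])
            tracks[[k]]$lastFrame <- f
          }
        }
      }
      for (di in which(!assigned)) {
        tracks[[length(tracks) + 1]] <-
          list(points = det[di, need, drop = FALSE], lastFrame = f)
      }
    }
  }
  ptsOut <- do.call(rbind, lapply(seq_along(tracks), function(k) {
    p <- tracks[[k]]$points
    data.frame(trackId = k, frame = p$frame, y = p$y, x = p$x)
  }))
  if (is.null(ptsOut))
    ptsOut <- data.frame(trackId = integer(), frame = integer(),
                         y = numeric(), x = numeric())
  metrics <- do.call(rbind, lapply(seq_along(tracks), function(k)
    cbind(trackId = k,
          trackMetrics(tracks[[k]]$points, pixelSizeUm, frameIntervalS))))
  if (is.null(metrics))
    metrics <- data.frame(trackId = integer(), nPoints = integer(),
                          displacementUm = numeric(),
                          pathLengthUm = numeric(),
                          meanSpeedUmS = numeric())
  metrics$motionClass <- motionClass(metrics$displacementUm,
                                     config$displacementThresholdUm)
  new("TrackSet", points = ptsOut, metrics = metrics,
      pixelSizeUm = pixelSizeUm, frameIntervalS = frameIntervalS,
      config = config)
}

motionClass <- function(displacementUm, thresholdUm) {
  factor(ifelse(displacementUm <= thresholdUm, "stationary", "dynamic"),
         levels = c("stationary", "dynamic"))
}

#' Classify tracks as stationary or dynamic
#'
#' Net displacement at most \code{thresholdUm} (0.67 um by default) is
#' stationary, above it dynamic. "Displacement" is the straight-line
#' first-to-last distance, not the path length (which is also reported by
#' \code{\link{trackMetrics}}).
#'
#' @param tracks a \linkS4class{TrackSet}.
#' @param thresholdUm displacement threshold in micrometres.
#' @return A list with \code{metrics} (the metrics table with an updated
#'   \code{motionClass}) and \code{counts}
#'   (\code{nStationary}, \code{nDynamic}, \code{nTotal}).
#' @export
classifyTracks <- function(tracks,
                           thresholdUm = tracks@config$displacementThresholdUm) {
  stopifnot(is(tracks, "TrackSet"))
  m <- tracks@metrics
  m$motionClass <- motionClass(m$displacementUm, thresholdUm)
  counts <- c(nStationary = sum(m$motionClass == "stationary"),
              nDynamic = sum(m$motionClass == "dynamic"),
              nTotal = nrow(m))
  list(metrics = m, counts = counts)
}

#' @rdname TrackSet-class
#' @aliases trackPoints trackMetricsTable
#' @export
setMethod("trackPoints", "TrackSet", function(x) x@points)

#' @rdname TrackSet-class
#' @export
setMethod("trackMetricsTable", "TrackSet", function(x) x@metrics)

setMethod("show", "TrackSet", function(object) {
  cts <- table(object@metrics$motionClass)
  cat(sprintf(paste0("TrackSet: %d tracks (%d stationary, %d dynamic at ",
                     "%g um), %d points\n"),
              nrow(object@metrics), cts["stationary"], cts["dynamic"],
              object@config$displacementThresholdUm, nrow(object@points)))
})
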