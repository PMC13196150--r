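#' ImageStack: an n-dimensional intensity raster with axis semantics
#'
#' The central raster container. \code{data} is an array whose dimensions
#' correspond one-to-one to \code{axes}, drawn from
#' \code{time}, \code{z}, \code{channel}, \code{y}, \code{x} (y and x are
#' always present and always the last two axes). Pixel size is isotropic
#' in-plane and given in micrometres; the frame interval in seconds is
#' \code{NA} when there is no time axis.
#'
#' @slot data numeric array of finite, non-negative intensities.
#' @slot axes character vector of axis labels, same length as \code{dim(data)}.
#' @slot pixelSizeUm micrometres per pixel (> 0).
#' @slot frameIntervalS seconds per time frame, or \code{NA}.
#' @exportClass ImageStack
setClass("ImageStack",
  slots = c(data = "array", axes = "character",
            pixelSizeUm = "numeric", frameIntervalS = "numeric"))

.AXIS_NAMES <- c("time", "z", "channel", "y", "x")

setValidity("ImageStack", function(object) {
  msg <- character()
  d <- object@data
  ax <- object@axes
  if (length(dim(d)) != length(ax))
    msg <- c(msg, "length(axes) must equal length(dim(data))")
  if (anyDuplicated(ax))
    msg <- c(msg, "axis labels must be unique")
  if (!all(ax %in% .AXIS_NAMES))
    msg <- c(msg, sprintf("axis labels must be in {%s}",
                          paste(.AXIS_NAMES, collapse = ", ")))
  if (!all(c("y", "x") %in% ax))
    msg <- c(msg, "axes y and x are required")
  if (length(ax) >= 2 && !identical(tail(ax, 2), c("y", "x")))
    msg <- c(msg, "y and x must be the last two axes")
  if (!all(is.finite(d)) || any(d < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (length(object@pixelSizeUm) != 1 || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  fi <- object@frameIntervalS
  if (length(fi) != 1) msg <- c(msg, "frameIntervalS must be length 1")
  else if (!is.na(fi) && (!is.finite(fi) || fi <= 0))
    msg <- c(msg, "frameIntervalS must be > 0 when present")
  if (length(msg)) msg else TRUE
})

#' LabelMap: integer-labeled segmentation raster
#'
#' 0 is background; labels are exactly 1..nLabels, each occupied by at least
#' one pixel, and each label's pixel set is connected under the package's
#' 8-connectivity convention.
#'
#' @slot data integer matrix of labels.
#' @slot nLabels number of labels.
#' @exportClass LabelMap
setClass("LabelMap", slots = c(data = "matrix", nLabels = "integer"))

setValidity("LabelMap", function(object) {
  d <- object@data
  n <- object@nLabels
  if (!is.numeric(d)) return("label data must be numeric")
  u <- sort(unique(as.integer(d)))
  want <- 0:n
  if (!all(u %in% want)) return("labels outside {0..nLabels}")
  if (n > 0 && !all(seq_len(n) %in% u)) return("empty label value present")
  TRUE
})

#' ThresholdResult: an automatic intensity threshold
#'
#' @slot method one of \code{huang}, \code{triangle}, \code{otsu}.
#' @slot value threshold in the image's gray-level units (lower edge of the
#'   first foreground bin); foreground is \code{intensity > value}.
#' @slot bin 0-based index of the first foreground histogram bin.
#' @exportClass ThresholdResult
setClass("ThresholdResult",
  slots = c(method = "character", value = "numeric", bin = "integer"))

setValidity("ThresholdResult", function(object) {
  if (!object@method %in% c("huang", "triangle", "otsu"))
    return("unknown method")
  if (length(object@value) != 1 || !is.finite(object@value))
    return("value must be a single finite number")
  TRUE
})

#' ColocConfig: parameters of the TIRF colocalization stage
#'
#' @slot medianRadius disk radius (pixels) of the reference-channel median
#'   pre-filter used for cell masking; default 4.
#' @slot dogSigmas small and large Gaussian sigmas (pixels) of the
#'   difference-of-Gaussians spot enhancement.
#' @slot spotSigma,outlineSigma sigmas (pixels) of the Voronoi-Otsu seed and
#'   outline blurs.
#' @slot cutHigh,cutLow overlap-score class cut-offs: score >= cutHigh is
#'   colocalized, score < cutLow is non-colocalized, otherwise partial.
#' @slot reciprocal also score reference-channel vesicles against the
#'   query-channel mask.
#' @slot queryChannel,referenceChannel 1-based channel indices.
#' @slot maskStrategy \code{external}, \code{threshold_fallback} or
#'   \code{manual}.
#' @exportClass ColocConfig
setClass("ColocConfig",
  slots = c(medianRadius = "integer", dogSigmas = "numeric",
            spotSigma = "numeric", outlineSigma = "numeric",
            cutHigh = "numeric", cutLow = "numeric",
            reciprocal = "logical",
            queryChannel = "integer", referenceChannel = "integer",
            maskStrategy = "character"))

setValidity("ColocConfig", function(object) {
  msg <- character()
  if (object@medianRadius < 0) msg <- c(msg, "medianRadius must be >= 0")
  if (length(object@dogSigmas) != 2 ||
      !(object@dogSigmas[1] >= 0 && object@dogSigmas[1] < object@dogSigmas[2]))
    msg <- c(msg, "dogSigmas must satisfy 0 <= small < large")
  if (!(object@cutLow > 0 && object@cutLow < object@cutHigh &&
        object@cutHigh <= 1))
    msg <- c(msg, "cut-offs must satisfy 0 < cutLow < cutHigh <= 1")
  if (object@queryChannel == object@referenceChannel)
    msg <- c(msg, "query and reference channels must differ")
  if (!object@maskStrategy %in% c("external", "threshold_fallback", "manual"))
    msg <- c(msg, "unknown maskStrategy")
  if (length(msg)) msg else TRUE
})

#' MembraneQuantResult: per-cell membrane/cytosol quantification
#'
#' @slot cellId connected-component id of the cell.
#' @slot wholeCellMask,cytosolMask,membraneMask logical matrices; the
#'   membrane mask is the whole-cell mask minus the eroded cytosol mask.
#' @slot meanWhole,meanCytosol,meanMembrane mean intensities on the
#'   measurement plane.
#' @slot relativeMembraneIntensity meanMembrane / meanWhole.
#' @slot membraneCytosolRatio meanMembrane / meanCytosol.
#' @exportClass MembraneQuantResult
setClass("MembraneQuantResult",
  slots = c(cellId = "integer",
            wholeCellMask = "matrix", cytosolMask = "matrix",
            membraneMask = "matrix",
            meanWhole = "numeric", meanCytosol = "numeric",
            meanMembrane = "numeric",
            relativeMembraneIntensity = "numeric",
            membraneCytosolRatio = "numeric"))

setValidity("MembraneQuantResult", function(object) {
  w <- object@wholeCellMask; cy <- object@cytosolMask; mb <- object@membraneMask
  if (!identical(dim(w), dim(cy)) || !identical(dim(w), dim(mb)))
    return("mask shapes differ")
  if (any(cy & !w)) return("cytosol mask not contained in whole-cell mask")
  if (!identical(mb, w & !cy)) return("membrane mask must be whole \\ cytosol")
  if (any(mb & cy)) return("membrane and cytosol masks overlap")
  TRUE
})

#' VolumeColocResult: percent-volume overlap of two thresholded channels
#'
#' @slot thresholdA,thresholdB intensity thresholds applied to each channel.
#' @slot nA,nB,nAB supra-threshold voxel counts (A, B, both).
#' @slot percentAinB,percentBinA percentage of each channel's supra-threshold
#'   volume overlapping the other's; \code{NA} when the denominator is empty.
#' @exportClass VolumeColocResult
setClass("VolumeColocResult",
  slots = c(thresholdA = "numeric", thresholdB = "numeric",
            nA = "integer", nB = "integer", nAB = "integer",
            percentAinB = "numeric", percentBinA = "numeric"))

setValidity("VolumeColocResult", function(object) {
  if (object@nAB > object@nA || object@nAB > object@nB)
    return("overlap count exceeds a channel count")
  p <- c(object@percentAinB, object@percentBinA)
  p <- p[!is.na(p)]
  if (any(p < 0 | p > 100)) return("percentages must lie in [0, 100]")
  TRUE
})

#' TrackSet: linked vesicle trajectories with motion metrics
#'
#' @slot points data.frame with columns \code{trackId}, \code{frame} (0-based),
#'   \code{y}, \code{x} (0-based pixels).
#' @slot metrics one row per track: \code{trackId}, \code{nPoints},
#'   \code{displacementUm}, \code{pathLengthUm}, \code{meanSpeedUmS},
#'   \code{motionClass} (\code{stationary}/\code{dynamic}).
#' @slot pixelSizeUm,frameIntervalS physical calibration.
#' @slot config linking/classification parameters used.
#' @exportClass TrackSet
setClass("TrackSet",
  slots = c(points = "data.frame", metrics = "data.frame",
            pixelSizeUm = "numeric", frameIntervalS = "numeric",
            config = "list"))

setValidity("TrackSet", function(object) {
  pts <- object@points
  need <- c("trackId", "frame", "y", "x")
  if (!all(need %in% names(pts))) return("points missing required columns")
  if (nrow(pts)) {
    byTrack <- split(pts$frame, pts$trackId)
    if (!all(vapply(byTrack, function(f) all(diff(f) > 0), logical(1))))
      return("frames must be strictly increasing within each track")
  }
  m <- object@metrics
  if (nrow(m) &&
      any(m$displacementUm > m$pathLengthUm + 1e-9))
    return("displacement exceeds path length")
  TRUE
})

#' GroundTruth: a synthetic generator's record of what it drew
#'
#' @slot type \code{tirf}, \code{confocal_cell} or \code{tracks}.
#' @slot records data.frame of true per-object entries (spot positions and
#'   colocalization flags; track points and classes).
#' @slot params generator parameters after defaulting.
#' @slot rasters noiseless twin rasters and masks, where applicable.
#' @slot seed the seed the generator was called with.
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(type = "character", records = "data.frame", params = "list",
            rasters = "list", seed = "integer"))

#' GroupComparison: two-group summary with Student's t test
#'
#' @slot labels group names.
#' @slot n,groupMean,groupSem per-group sample size, mean and standard error
#'   of the mean (sd / sqrt(n)).
#' @slot statistic,df,pValue t statistic, degrees of freedom, two-sided p.
#' @slot stars significance marker at 0.05 / 0.01 / 0.001.
#' @slot welch whether the unequal-variance form was used.
#' @exportClass GroupComparison
setClass("GroupComparison",
  slots = c(labels = "character", n = "integer",
            groupMean = "numeric", groupSem = "numeric",
            statistic = "numeric", df = "numeric", pValue = "numeric",
            stars = "character", welch = "logical"))
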