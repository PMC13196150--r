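resolveThreshold <- function(channel, threshold, name) {
  if (is.character(threshold)) {
    if (!startsWith(threshold, "auto:"))
      stop(name, ": character thresholds must be 'auto:<method>'",
           call. = FALSE)
    autoThreshold(channel, sub("^auto:", "", threshold))@value
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    threshold
  }
}

#' Percent-volume overlap between two thresholded channels
#'
#' The intensity-threshold colocalization statistic: with supra-threshold
#' voxel sets \eqn{A = \{v: a(v) > t_A\}} and \eqn{B = \{v: b(v) > t_B\}},
#' \deqn{percentAinB = 100 \cdot |A \cap B| / |A|,}
#' asymmetric by construction; both directions are reported. Thresholds are
#' user-supplied intensities (the published analyses adjusted them manually
#' per image) or \code{"auto:otsu"}-style automatic methods. When a channel
#' has no supra-threshold voxel its percentage is \code{NA} (undefined, not
#' zero).
#'
#' @param channelA,channelB aligned numeric matrices or 3D arrays.
#' @param thresholdA,thresholdB numeric thresholds or \code{"auto:<method>"}
#'   with method one of huang/triangle/otsu.
#' @param mask optional logical array restricting the analysis (e.g. one
#'   cell); same shape as the channels.
#' @return A \linkS4class{VolumeColocResult}.
#' @examples
#' a <- array(runif(16^3), c(16, 16, 16))
#' percentVolumeOverlap(a, a, 0.5, 0.5)   # identical channels: 100%
#' @export
percentVolumeOverlap <- function(channelA, channelB, thresholdA, thresholdB,
                                 mask = NULL) {
  if (!identical(dim(channelA), dim(channelB)))
    stop("channel shapes differ", call. = FALSE)
  tA <- resolveThreshold(channelA, thresholdA, "thresholdA")
  tB <- resolveThreshold(channelB, thresholdB, "thresholdB")
  inA <- channelA > tA
  inB <- channelB > tB
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(channelA)))
      stop("mask shape differs from channels", call. = FALSE)
    inA <- inA & mask
    inB <- inB & mask
  }
  nA <- sum(inA); nB <- sum(inB); nAB <- sum(inA & inB)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  if (nA == 0)
    warning("no voxel above thresholdA: percentAinB is undefined")
  new("VolumeColocResult", thresholdA = tA, thresholdB = tB,
      nA = as.integer(nA), nB = as.integer(nB), nAB = as.integer(nAB),
      percentAinB = pct(nAB, nA), percentBinA = pct(nAB, nB))
}

setMethod("show", "VolumeColocResult", function(object) {
  cat(sprintf(paste0("VolumeColocResult: tA = %g, tB = %g, |A| = %d, ",
                     "|B| = %d, |A&B| = %d\n  A in B: %s%%   B in A: %s%%\n"),
              object@thresholdA, object@thresholdB, object@nA, object@nB,
              object@nAB, format(object@percentAinB),
              format(object@percentBinA)))
})
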