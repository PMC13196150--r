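# Bilinear interpolation at 0-based (y, x); coordinates clamped to the image.
bilinearSample <- function(plane, y, x) {
  nr <- nrow(plane); nc <- ncol(plane)
  y <- pmin(pmax(y, 0), nr - 1)
  x <- pmin(pmax(x, 0), nc - 1)
  y0 <- pmin(floor(y), nr - 2); y0 <- pmax(y0, 0)
  x0 <- pmin(floor(x), nc - 2); x0 <- pmax(x0, 0)
  fy <- y - y0; fx <- x - x0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  plane[i00] * (1 - fy) * (1 - fx) + plane[i01] * (1 - fy) * fx +
    plane[i10] * fy * (1 - fx) + plane[i11] * fy * fx
}

#' Line-scan intensity profile
#'
#' Samples intensities along the segment from \code{p0} to \code{p1} at
#' unit-pixel spacing (plus the exact endpoint) by bilinear interpolation,
#' averaged across \code{width} parallel lines offset perpendicular to the
#' segment at unit-pixel spacing. One profile is returned per channel and per
#' frame. Positions are reported in micrometres from \code{p0}.
#'
#' @param stack an \linkS4class{ImageStack} (or numeric matrix).
#' @param p0,p1 segment endpoints as 0-based \code{c(y, x)} pixels, distinct
#'   and inside the image.
#' @param width number of averaged parallel lines (odd values keep the
#'   segment centred); offset samples falling outside the image are clamped
#'   to the border.
#' @return data.frame with columns \code{frame}, \code{channel},
#'   \code{positionUm} (strictly increasing from 0 to the segment length)
#'   and \code{intensity}.
#' @export
lineProfile <- function(stack, p0, p1, width = 1L) {
  if (is.matrix(stack)) stack <- ImageStack(stack, "yx")
  stopifnot(is(stack, "ImageStack"), length(p0) == 2, length(p1) == 2)
  d <- dim(stackData(stack))
  nr <- d[length(d) - 1]; nc <- d[length(d)]
  pts <- rbind(p0, p1)
  if (any(pts[, 1] < 0 | pts[, 1] > nr - 1 | pts[, 2] < 0 | pts[, 2] > nc - 1))
    stop("endpoints must lie inside the image", call. = FALSE)
  if (all(p0 == p1)) stop("p0 and p1 must differ", call. = FALSE)
  dy <- p1[1] - p0[1]; dx <- p1[2] - p0[2]
  len <- sqrt(dy^2 + dx^2)
  uy <- dy / len; ux <- dx / len
  py <- -ux; px <- uy                       # unit perpendicular
  tpos <- seq(0, floor(len))
  if (tail(tpos, 1) < len) tpos <- c(tpos, len)
  offsets <- seq_len(width) - (width + 1) / 2
  nt <- max(axisLength(stack, "time"), 1L)
  nch <- max(axisLength(stack, "channel"), 1L)
  out <- list()
  for (t in seq_len(nt)) for (ch in seq_len(nch)) {
    plane <- getPlane(stack, time = t, channel = ch)
    acc <- rep(0, length(tpos))
    for (o in offsets) {
      ys <- p0[1] + tpos * uy + o * py
      xs <- p0[2] + tpos * ux + o * px
      acc <- acc + bilinearSample(plane, ys, xs)
    }
    out[[length(out) + 1]] <- data.frame(
      frame = t - 1L, channel = ch, positionUm = tpos * pixelSize(stack),
      intensity = acc / width)
  }
  do.call(rbind, out)
}
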