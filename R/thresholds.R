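#' Automatic threshold from a histogram
#'
#' Chooses the split index \code{s} (0-based, in \code{1..B-1}) between
#' background bins \code{0..s-1} and foreground bins \code{s..B-1} that
#' optimizes the requested objective:
#' \describe{
#'   \item{otsu}{maximizes the between-class variance
#'     \eqn{\omega_0\omega_1(\mu_0-\mu_1)^2}.}
#'   \item{huang}{minimizes the Huang--Wang fuzziness: each occupied gray
#'     level g gets membership \eqn{u = 1/(1 + |g-\mu_{class}|/C)} (C = range
#'     of occupied bins) and contributes \eqn{h(g)\,S(u)} with the Shannon
#'     entropy \eqn{S(u) = -u\log u - (1-u)\log(1-u)}.}
#'   \item{triangle}{finds the histogram peak (ties: lowest-intensity modal
#'     bin), takes the tail on the longer side of the peak, and returns the
#'     bin between peak and tail end at maximal perpendicular distance from
#'     the line joining \eqn{(peak, h_{peak})} to \eqn{(end, h_{end})}.}
#' }
#' Ties are broken toward the lower split everywhere.
#'
#' @param counts non-negative histogram counts (one per bin).
#' @param method \code{"huang"}, \code{"triangle"} or \code{"otsu"}.
#' @return The 0-based split index: the first foreground bin.
#' @export
thresholdFromHistogram <- function(counts,
                                   method = c("huang", "triangle", "otsu")) {
  method <- match.arg(method)
  counts <- as.numeric(counts)
  B <- length(counts)
  if (B < 2 || any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be >= 2 finite non-negative bins", call. = FALSE)
  nz <- which(counts > 0)
  if (length(nz) < 2)
    stop("histogram has fewer than two occupied bins (constant image)",
         call. = FALSE)
  g <- 0:(B - 1)
  switch(method,
    otsu = {
      cw <- cumsum(counts)
      cm <- cumsum(counts * g)
      total <- cw[B]; totalMean <- cm[B] / total
      s <- 1:(B - 1)
      w0 <- cw[s]; w1 <- total - w0
      valid <- w0 > 0 & w1 > 0
      mu0 <- cm[s] / w0
      mu1 <- (cm[B] - cm[s]) / w1
      obj <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
      s[which.max(obj)]                 # which.max takes the first (lowest s)
    },
    huang = {
      C <- max(nz) - min(nz)
      cw <- cumsum(counts)
      cm <- cumsum(counts * g)
      total <- cw[B]
      entropy <- function(u) {
        v <- 1 - u
        -ifelse(u > 0, u * log(u), 0) - ifelse(v > 0, v * log(v), 0)
      }
      best <- NULL; bestE <- Inf
      for (s in 1:(B - 1)) {
        w0 <- cw[s]; w1 <- total - w0
        if (w0 == 0 || w1 == 0) next
        mu0 <- cm[s] / w0
        mu1 <- (cm[B] - cm[s]) / w1
        mu <- ifelse(g < s, mu0, mu1)
        u <- 1 / (1 + abs(g - mu) / C)
        E <- sum(counts * entropy(u))
        if (E < bestE) { bestE <- E; best <- s }
      }
      best
    },
    triangle = {
      modal <- which(counts == max(counts))
      p <- modal[1] - 1L                 # lowest-intensity modal bin, 0-based
      lo <- min(nz) - 1L; hi <- max(nz) - 1L
      e <- if ((hi - p) >= (p - lo)) hi else lo   # longer side; tie -> right
      a <- min(p, e); b <- max(p, e)
      if (b - a < 2) return(max(a, 1L))
      xs <- (a + 1L):(b - 1L)
      ys <- counts[xs + 1L]
      yp <- counts[p + 1L]; ye <- counts[e + 1L]
      # |cross product| of (end-peak) with (point-peak); denominator constant
      d <- abs((ye - yp) * (xs - p) - (e - p) * (ys - yp))
      xs[which.max(d)]
    })
}

#' Automatic intensity threshold of an image
#'
#' Builds a 256 equal-width-bin histogram spanning \code{[min, max]} of the
#' image (regardless of bit depth) and applies
#' \code{\link{thresholdFromHistogram}}. The returned threshold is the lower
#' edge of the first foreground bin, so foreground is
#' \code{intensity > value}; for a perfectly bimodal image all three methods
#' place it strictly between the modes.
#'
#' @param plane numeric matrix or array with at least two distinct values.
#' @param method \code{"huang"}, \code{"triangle"} or \code{"otsu"}.
#' @param nBins number of histogram bins (256 by default).
#' @return A \linkS4class{ThresholdResult}.
#' @examples
#' img <- matrix(c(rep(10, 60), rep(200, 40)), 10, 10)
#' autoThreshold(img, "otsu")
#' @export
autoThreshold <- function(plane, method = c("huang", "triangle", "otsu"),
                          nBins = 256L) {
  method <- match.arg(method)
  v <- as.numeric(plane)
  if (!all(is.finite(v))) stop("non-finite intensities", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (hi <= lo)
    stop("constant image: no threshold exists", call. = FALSE)
  width <- (hi - lo) / nBins
  bin <- pmin(floor((v - lo) / width), nBins - 1)
  counts <- tabulate(bin + 1L, nbins = nBins)
  s <- thresholdFromHistogram(counts, method)
  new("ThresholdResult", method = method, value = lo + s * width,
      bin = as.integer(s))
}

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult(%s): value = %g (bin %d)\n",
              object@method, object@value, object@bin))
})

#' @rdname autoThreshold
#' @param x a \linkS4class{ThresholdResult}.
#' @export
thresholdValue <- function(x) {
  stopifnot(is(x, "ThresholdResult"))
  x@value
}

#' Binarize an image at a threshold
#'
#' @param plane numeric matrix/array.
#' @param threshold a number or a \linkS4class{ThresholdResult}.
#' @return Logical mask, \code{plane > threshold}.
#' @export
applyThreshold <- function(plane, threshold) {
  if (is(threshold, "ThresholdResult")) threshold <- threshold@value
  plane > threshold
}
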