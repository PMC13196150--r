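# Reflected index lookup (scipy-style 'reflect': d c b a | a b c d), applied
# repeatedly so kernels wider than the image stay valid.
reflectIndex <- function(p, n) {
  repeat {
    below <- p < 1; above <- p > n
    if (!any(below) && !any(above)) return(p)
    p[below] <- 1L - p[below]
    p[above] <- 2L * n + 1L - p[above]
  }
}

# Separable 1D convolution along rows with reflect boundary.
convolveRows <- function(m, kernel, r) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in -r:r) {
    idx <- reflectIndex(seq_len(n) + j, n)
    out <- out + kernel[j + r + 1] * m[idx, , drop = FALSE]
  }
  out
}

#' Gaussian blur of a 2D plane
#'
#' Isotropic Gaussian convolution, implemented separably with the kernel
#' truncated at 4 sigma and reflect boundary handling. \code{sigma = 0}
#' returns the input unchanged; constants are preserved exactly (the kernel is
#' normalized after truncation).
#'
#' @param plane numeric matrix.
#' @param sigma standard deviation in pixels (>= 0).
#' @return Numeric matrix of the same shape.
#' @export
gaussianBlur <- function(plane, sigma) {
  stopifnot(is.matrix(plane), is.numeric(plane))
  if (length(sigma) != 1 || !is.finite(sigma) || sigma < 0)
    stop("sigma must be a single number >= 0", call. = FALSE)
  if (sigma == 0) return(plane)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  t(convolveRows(t(convolveRows(plane, k, r)), k, r))
}

#' Median filter over a disk neighborhood
#'
#' Each pixel is replaced by the median over the discrete disk
#' \eqn{\{(dy,dx): dy^2+dx^2 \le r^2\}} centred on it, with reflect boundary
#' handling. \code{radius = 0} is the identity. The default radius of 4 is the
#' pre-filter used before cell masking in the TIRF stage.
#'
#' @param plane numeric matrix.
#' @param radius integer radius in pixels (>= 0).
#' @return Numeric matrix of the same shape.
#' @export
diskMedianFilter <- function(plane, radius = 4L) {
  stopifnot(is.matrix(plane), is.numeric(plane))
  if (length(radius) != 1 || is.na(radius) || radius < 0 ||
      radius != round(radius))
    stop("radius must be a single integer >= 0", call. = FALSE)
  if (radius == 0) return(plane)
  cpp_disk_median(plane, as.integer(radius))
}

#' Difference-of-Gaussians spot enhancement
#'
#' \code{gaussianBlur(plane, sigmaSmall) - gaussianBlur(plane, sigmaLarge)},
#' with negative values clipped to zero so the result is a non-negative
#' enhancement map suitable for spot labeling. Constants map to zero.
#'
#' @param plane numeric matrix.
#' @param sigmaSmall,sigmaLarge band-pass sigmas in pixels,
#'   \code{0 <= sigmaSmall < sigmaLarge}.
#' @return Non-negative numeric matrix.
#' @export
dogFilter <- function(plane, sigmaSmall = 1, sigmaLarge = 4) {
  if (!(sigmaSmall >= 0 && sigmaSmall < sigmaLarge))
    stop("need 0 <= sigmaSmall < sigmaLarge", call. = FALSE)
  pmax(gaussianBlur(plane, sigmaSmall) - gaussianBlur(plane, sigmaLarge), 0)
}
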