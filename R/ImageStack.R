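#' Construct an ImageStack
#'
#' @param data numeric array (or matrix) of non-negative intensities.
#' @param axes axis labels, either a character vector of full names
#'   (\code{"time"}, \code{"z"}, \code{"channel"}, \code{"y"}, \code{"x"}) or a
#'   compact string such as \code{"tcyx"}; must match \code{dim(data)} and end
#'   in y, x.
#' @param pixelSizeUm micrometres per pixel (isotropic in-plane).
#' @param frameIntervalS seconds per time frame; \code{NA} when no time axis.
#' @return An \linkS4class{ImageStack}.
#' @examples
#' s <- ImageStack(array(0, c(3, 8, 8)), "zyx", pixelSizeUm = 0.1)
#' stackAxes(s)
#' @export
ImageStack <- function(data, axes, pixelSizeUm = 1, frameIntervalS = NA_real_) {
  if (is.matrix(data)) data <- array(data, dim = dim(data))
  storage.mode(data) <- "double"
  ax <- parseAxes(axes)
  if (length(ax) != length(dim(data)))
    stop("axis_spec does not match data shape: ", length(ax), " axes for ",
         length(dim(data)), " dimensions", call. = FALSE)
  new("ImageStack", data = data, axes = ax,
      pixelSizeUm = as.numeric(pixelSizeUm),
      frameIntervalS = as.numeric(frameIntervalS))
}

# Accepts "tcyx"-style compact strings or full names.
parseAxes <- function(axes) {
  if (length(axes) == 1 && !axes %in% .AXIS_NAMES) {
    letters1 <- strsplit(axes, "")[[1]]
    map <- c(t = "time", z = "z", c = "channel", y = "y", x = "x")
    if (!all(letters1 %in% names(map)))
      stop("unknown axis letter in '", axes, "'", call. = FALSE)
    unname(map[letters1])
  } else as.character(axes)
}

#' @rdname ImageStack-class
#' @aliases stackData stackAxes pixelSize frameInterval
#' @export
setMethod("stackData", "ImageStack", function(x) x@data)

#' @rdname ImageStack-class
#' @export
setMethod("stackAxes", "ImageStack", function(x) x@axes)

#' @rdname ImageStack-class
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSizeUm)

#' @rdname ImageStack-class
#' @export
setMethod("frameInterval", "ImageStack", function(x) x@frameIntervalS)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat("ImageStack:", paste(sprintf("%s=%d", object@axes, d), collapse = " "),
      "\n  pixel size:", object@pixelSizeUm, "um/px")
  if (!is.na(object@frameIntervalS))
    cat("; frame interval:", object@frameIntervalS, "s")
  cat("\n  intensity range: [", min(object@data), ",", max(object@data), "]\n")
})

#' Axis length of an ImageStack
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param axis axis name (full or single-letter).
#' @return Integer length, or 0 when the axis is absent.
#' @export
axisLength <- function(stack, axis) {
  ax <- parseAxes(axis)
  i <- match(ax, stack@axes)
  if (is.na(i)) 0L else dim(stack@data)[i]
}

#' Extract one 2D plane from an ImageStack
#'
#' Non-spatial axes are indexed 1-based; omitted axes of length 1 are dropped
#' automatically.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param time,z,channel 1-based indices along the respective axes (ignored
#'   when the axis is absent).
#' @return A numeric y-by-x matrix.
#' @export
getPlane <- function(stack, time = 1L, z = 1L, channel = 1L) {
  idx <- lapply(stack@axes, function(a)
    switch(a, time = time, z = z, channel = channel, y = TRUE, x = TRUE))
  pl <- do.call(`[`, c(list(stack@data), idx, list(drop = FALSE)))
  dims <- dim(pl)
  matrix(pl, nrow = dims[length(dims) - 1], ncol = dims[length(dims)])
}

#' Read a TIFF file into an ImageStack
#'
#' Multi-page TIFFs are read page by page; pages are unrolled into the
#' non-spatial axes of \code{axes} in row-major order (first listed axis
#' slowest). Pixel size and frame interval are not taken from the file; supply
#' them (e.g. from an acquisition config) when they matter.
#'
#' @param path TIFF file (8/16-bit unsigned or 32-bit float, grayscale pages).
#' @param axes axis specification, e.g. \code{"tyx"} or \code{"zcyx"}.
#' @inheritParams ImageStack
#' @return An \linkS4class{ImageStack}.
#' @export
readStack <- function(path, axes, pixelSizeUm = 1, frameIntervalS = NA_real_) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  axisLengths <- NULL
  if (!is.null(names(axes))) {            # named form: c(time = 20, channel = 2)
    axisLengths <- suppressWarnings(as.integer(axes))
    axes <- names(axes)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) {
      if (dim(p)[3] != 1)
        stop("multi-sample TIFF pages are not supported; ",
             "write channels as separate pages", call. = FALSE)
      p <- p[, , 1]
    }
    p
  })
  ax <- parseAxes(axes)
  lead <- setdiff(ax, c("y", "x"))
  nlead <- length(lead)
  npages <- length(pages)
  dims2 <- dim(pages[[1]])
  if (nlead == 0) {
    if (npages != 1)
      stop("axis_spec has no page axis but file has ", npages, " pages",
           call. = FALSE)
    return(ImageStack(pages[[1]], ax, pixelSizeUm, frameIntervalS))
  }
  # infer leading-axis lengths: a single page axis takes all pages; with two
  # page axes the caller appends lengths like "t2z5" -> not supported; instead
  # the page count must factor as given via attr; we accept axes with explicit
  # lengths through the `axes` vector form c(time = 4, channel = 2).
  if (!is.null(axisLengths)) {
    leadLen <- axisLengths[match(lead, ax)]
  } else if (nlead == 1) {
    if (npages == 1)
      stop("axis '", lead, "' requested but the file has a single page; ",
           "drop the axis or pass an explicit length", call. = FALSE)
    leadLen <- npages
  } else {
    stop("for more than one non-spatial axis, pass named lengths, e.g. ",
         "axes = c(time = 20, channel = 2, y = NA, x = NA)", call. = FALSE)
  }
  if (prod(leadLen) != npages)
    stop("axis_spec implies ", prod(leadLen), " pages but file has ", npages,
         call. = FALSE)
  arr <- array(0, dim = c(leadLen, dims2))
  # pages are row-major over the leading axes (first axis slowest)
  for (i in seq_len(npages)) {
    idx <- vector("list", nlead)
    rem <- i - 1L
    for (j in rev(seq_len(nlead))) {        # last axis fastest
      idx[[j]] <- (rem %% leadLen[j]) + 1L
      rem <- rem %/% leadLen[j]
    }
    arr <- do.call(`[<-`, c(list(arr), idx, list(TRUE, TRUE),
                            list(value = pages[[i]])))
  }
  ImageStack(arr, c(lead, "y", "x"), pixelSizeUm, frameIntervalS)
}

#' Write an ImageStack (or mask) as a multi-page TIFF
#'
#' Non-spatial axes are unrolled into pages in row-major order (first axis
#' slowest), mirroring \code{\link{readStack}}. Intensities are stored as
#' unsigned integers of the requested bit depth and are clipped and rounded;
#' masks are written as 8-bit \{0, 255\}.
#'
#' @param x an \linkS4class{ImageStack}, numeric matrix/array, or logical
#'   matrix/array (mask).
#' @param path output file.
#' @param bitsPerSample 8 or 16 (ignored for masks, which are 8-bit).
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(x, path, bitsPerSample = 16L) {
  if (is(x, "ImageStack")) x <- x@data
  if (is.logical(x)) {
    x <- array(as.numeric(x), dim = dim(x))
    x <- x * 255
    bitsPerSample <- 8L
  }
  maxval <- 2^bitsPerSample - 1
  x <- pmin(pmax(round(x), 0), maxval) / maxval
  d <- dim(x)
  nd <- length(d)
  if (nd == 2) {
    tiff::writeTIFF(x, path, bits.per.sample = bitsPerSample)
    return(invisible(path))
  }
  lead <- d[seq_len(nd - 2)]
  npages <- prod(lead)
  pages <- vector("list", npages)
  for (i in seq_len(npages)) {
    idx <- vector("list", nd - 2)
    rem <- i - 1L
    for (j in rev(seq_len(nd - 2))) {
      idx[[j]] <- (rem %% lead[j]) + 1L
      rem <- rem %/% lead[j]
    }
    pl <- do.call(`[`, c(list(x), idx, list(TRUE, TRUE), list(drop = FALSE)))
    pages[[i]] <- matrix(pl, nrow = d[nd - 1], ncol = d[nd])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample)
  invisible(path)
}

#' Sum-slices z-projection
#'
#' Collapses the z axis by summation, preserving total intensity; all other
#' axes are unchanged.
#'
#' @param stack an \linkS4class{ImageStack} with a z axis.
#' @return An \linkS4class{ImageStack} without a z axis.
#' @export
sumProjection <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  zi <- match("z", stack@axes)
  if (is.na(zi)) stop("stack has no z axis", call. = FALSE)
  d <- stack@data
  keep <- setdiff(seq_along(dim(d)), zi)
  out <- apply(d, keep, sum)
  if (!is.array(out)) out <- array(out, dim = length(out))
  if (is.matrix(out)) out <- array(out, dim = dim(out))
  ImageStack(out, stack@axes[keep], stack@pixelSizeUm, stack@frameIntervalS)
}
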