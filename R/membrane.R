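#' Whole-cell segmentation of a fluorescence projection
#'
#' Gaussian blur, Huang threshold, hole filling and size filtering, yielding
#' one label per surviving cell. An image with no surviving component returns
#' an empty \linkS4class{LabelMap} rather than an error.
#'
#' @param projection numeric matrix (a sum projection or single plane).
#' @param blurSigma Gaussian sigma in pixels before thresholding. The default
#'   of 0 (no blur) is deliberate: a sum projection is already shot-noise
#'   averaged, and any pre-threshold blur dilates the mask by roughly
#'   2--4 sigma of background-valued pixels, which later contaminate the
#'   fixed-width membrane band; stray supra-threshold noise pixels are
#'   removed by the size filter instead. Raise it for noisy single planes.
#' @param sizeBounds inclusive component-area bounds in pixels; default
#'   \code{c(500, Inf)} discards debris-sized specks.
#' @return A \linkS4class{LabelMap} of cells.
#' @export
wholeCellMask <- function(projection, blurSigma = 0,
                          sizeBounds = c(500, Inf)) {
  stopifnot(is.matrix(projection), is.numeric(projection))
  blurred <- gaussianBlur(projection, blurSigma)
  if (max(blurred) <= min(blurred))
    return(new("LabelMap",
               data = matrix(0L, nrow(projection), ncol(projection)),
               nLabels = 0L))
  thr <- autoThreshold(blurred, "huang")
  mask <- applyThreshold(blurred, thr)
  mask <- fillHoles(mask)
  mask <- sizeFilter(mask, sizeBounds[1], sizeBounds[2])
  labelMask(mask)
}

#' Quantify plasma-membrane versus cytosol fluorescence
#'
#' Reproduces the sum-projection membrane quantification: the z-stack is
#' sum-projected (if a z axis is present), each cell is segmented with
#' \code{\link{wholeCellMask}}, the cytosol mask is the whole-cell mask eroded
#' for \code{erodeCycles} cycles, and the membrane mask is their difference
#' (a band of roughly \code{erodeCycles} pixels, so the band width is
#' resolution-dependent). Mean intensities are measured on the original
#' projection. Two normalizations are reported per cell:
#' \code{relativeMembraneIntensity = meanMembrane / meanWhole} (the headline
#' metric) and \code{membraneCytosolRatio = meanMembrane / meanCytosol}.
#'
#' @param stack an \linkS4class{ImageStack} (z optional, single channel used)
#'   or a numeric matrix.
#' @param channel 1-based channel to quantify when a channel axis is present.
#' @param blurSigma,sizeBounds passed to \code{\link{wholeCellMask}}.
#' @param erodeCycles erosion cycles defining the cytosol mask (default 10).
#' @param element erosion structuring element (see \code{\link{erodeMask}}).
#'   The default is the 4-connected cross: iterating the 3x3 square measures
#'   erosion depth in the Chebyshev metric, so a 10-cycle band reaches
#'   10*sqrt(2) = 14 px on diagonal boundaries and overshoots a 12 px
#'   membrane ring there, whereas the cross stays within 10 px everywhere.
#' @return A list of \linkS4class{MembraneQuantResult}, one per cell;
#'   empty when no cell survives segmentation.
#' @seealso \code{\link{membraneTable}} for a tabular summary.
#' @export
quantifyMembrane <- function(stack, channel = 1L, blurSigma = 0,
                             sizeBounds = c(500, Inf), erodeCycles = 10L,
                             element = "cross") {
  if (is.matrix(stack)) {
    projection <- stack
  } else {
    stopifnot(is(stack, "ImageStack"))
    if ("z" %in% stackAxes(stack)) stack <- sumProjection(stack)
    if ("time" %in% stackAxes(stack))
      stop("time series are not supported here; pass one time point",
           call. = FALSE)
    projection <- getPlane(stack, channel = channel)
  }
  cells <- wholeCellMask(projection, blurSigma, sizeBounds)
  out <- vector("list", cells@nLabels)
  for (k in seq_len(cells@nLabels)) {
    whole <- matrix(cells@data == k, nrow(projection), ncol(projection))
    cyt <- erodeMask(whole, erodeCycles, element)
    if (!any(cyt))
      stop("degenerate cell ", k, ": erosion for ", erodeCycles,
           " cycles annihilated the cytosol mask", call. = FALSE)
    memb <- maskDifference(whole, cyt)
    mw <- meanIntensity(projection, whole)
    mc <- meanIntensity(projection, cyt)
    mm <- meanIntensity(projection, memb)
    out[[k]] <- new("MembraneQuantResult", cellId = k,
                    wholeCellMask = whole, cytosolMask = cyt,
                    membraneMask = memb,
                    meanWhole = mw, meanCytosol = mc, meanMembrane = mm,
                    relativeMembraneIntensity = mm / mw,
                    membraneCytosolRatio = mm / mc)
  }
  out
}

setMethod("show", "MembraneQuantResult", function(object) {
  cat(sprintf(paste0("MembraneQuantResult cell %d: |whole| = %d px, ",
                     "mean whole/cytosol/membrane = %.3g/%.3g/%.3g, ",
                     "membrane/whole = %.3g\n"),
              object@cellId, sum(object@wholeCellMask), object@meanWhole,
              object@meanCytosol, object@meanMembrane,
              object@relativeMembraneIntensity))
})

#' Tabulate membrane quantification results
#'
#' @param results a \linkS4class{MembraneQuantResult} or a list of them, as
#'   returned by \code{\link{quantifyMembrane}}.
#' @param image optional image identifier column.
#' @return data.frame with one row per cell: areas, the three mean
#'   intensities, and both normalized ratios.
#' @export
membraneTable <- function(results, image = NA_character_) {
  if (is(results, "MembraneQuantResult")) results <- list(results)
  if (length(results) == 0)
    return(data.frame(image = character(), cellId = integer(),
                      areaWhole = integer(), areaCytosol = integer(),
                      areaMembrane = integer(), meanWhole = numeric(),
                      meanCytosol = numeric(), meanMembrane = numeric(),
                      relativeMembraneIntensity = numeric(),
                      membraneCytosolRatio = numeric()))
  rows <- lapply(results, function(r) {
    data.frame(image = image, cellId = r@cellId,
               areaWhole = sum(r@wholeCellMask),
               areaCytosol = sum(r@cytosolMask),
               areaMembrane = sum(r@membraneMask),
               meanWhole = r@meanWhole, meanCytosol = r@meanCytosol,
               meanMembrane = r@meanMembrane,
               relativeMembraneIntensity = r@relativeMembraneIntensity,
               membraneCytosolRatio = r@membraneCytosolRatio)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
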