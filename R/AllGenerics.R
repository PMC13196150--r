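#' @rdname ImageStack-class
#' @param object,x an object.
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))

#' @rdname ImageStack-class
#' @export
setGeneric("stackAxes", function(x) standardGeneric("stackAxes"))

#' @rdname ImageStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ImageStack-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname LabelMap-class
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))

#' @rdname LabelMap-class
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))

#' @rdname TrackSet-class
#' @export
setGeneric("trackPoints", function(x) standardGeneric("trackPoints"))

#' @rdname TrackSet-class
#' @export
setGeneric("trackMetricsTable", function(x) standardGeneric("trackMetricsTable"))
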