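#' Accessors for afmorph classes
#'
#' \code{heights} returns the raw height matrix (nm); \code{pixelSize} the
#' pixel spacing \code{c(x, y)} in nm; \code{sq} the RMS roughness of a
#' \linkS4class{RoughnessReport}; \code{labels} the label matrix of a
#' \linkS4class{GrainLabelMap}.
#'
#' @param x object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("heights", function(x) standardGeneric("heights"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("sq", function(x) standardGeneric("sq"))

#' @rdname accessors
#' @export
setGeneric("labels2D", function(x) standardGeneric("labels2D"))

#' @rdname accessors
#' @export
setMethod("heights", "HeightField", function(x) x@heights)

#' @rdname accessors
#' @export
setMethod("pixelSize", "HeightField", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("sq", "RoughnessReport", function(x) x@sq)

#' @rdname accessors
#' @export
setMethod("labels2D", "GrainLabelMap", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("pixelSize", "GrainLabelMap", function(x) x@pixelSize)

setMethod("dim", "HeightField", function(x) dim(x@heights))

setMethod("show", "HeightField", function(object) {
  d <- dim(object@heights)
  ps <- object@pixelSize
  cat(sprintf("HeightField: %d x %d pixels, %.4g x %.4g nm", d[1], d[2],
              d[2] * ps[1], d[1] * ps[2]), "\n")
  cat(sprintf("  pixel size: %.4g x %.4g nm; heights [%.3g, %.3g] %s\n",
              ps[1], ps[2], min(object@heights), max(object@heights),
              object@zUnits))
  if (nzchar(object@title)) cat("  title:", object@title, "\n")
})

setMethod("show", "RoughnessReport", function(object) {
  cat(sprintf("RoughnessReport: Sq = %.4g nm (mean %.4g nm, n = %d)\n",
              object@sq, object@meanHeight, object@nPixels))
})

setMethod("show", "HdcfCurve", function(object) {
  cat(sprintf("HdcfCurve along %s: %d lags, %.4g..%.4g nm\n", object@axis,
              length(object@lags), object@lags[1], max(object@lags)))
})

setMethod("show", "RippleMetrics", function(object) {
  if (object@detected)
    cat(sprintf(
      "RippleMetrics: periodicity %.4g nm, peak-to-peak amplitude %.4g nm (axis %s, prominence %.2f)\n",
      object@periodicity, object@amplitudePp, object@axis, object@prominence))
  else cat("RippleMetrics: no periodic modulation detected\n")
})

setMethod("show", "PowerSpectrum2D", function(object) {
  cat(sprintf("PowerSpectrum2D: %d x %d bins, window = %s\n",
              nrow(object@power), ncol(object@power), object@window))
})

setMethod("show", "GrainLabelMap", function(object) {
  cat(sprintf("GrainLabelMap: %d grains above %.4g nm (connectivity %d)\n",
              max(object@labels), object@threshold, object@connectivity))
})

setMethod("show", "SceneGroundTruth", function(object) {
  cat(sprintf("SceneGroundTruth: %d planted aggregates, substrate %s\n",
              length(object@trueVolumes),
              paste(dim(object@substrateField@heights), collapse = " x ")))
})
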