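#' HeightField: a physical raster of surface heights
#'
#' The universal currency of the pipeline: a rectangular raster of surface
#' heights in nanometres with a known pixel spacing. Rows run top to bottom
#' (y increases downward), columns left to right; the physical coordinate of
#' pixel \code{[i, j]} is \code{x = (j - 1) * pixelSize(x)[1]},
#' \code{y = (i - 1) * pixelSize(x)[2]}, origin at the top-left pixel centre.
#'
#' @slot heights numeric matrix of heights (nm).
#' @slot pixelSize numeric(2), pixel spacing along x (columns) and y (rows), nm.
#' @slot title free-text image title.
#' @slot zUnits unit string for the height axis (normally \code{"nm"}).
#'
#' @aliases HeightField-class
#' @exportClass HeightField
setClass("HeightField",
  representation(heights = "matrix", pixelSize = "numeric",
                 title = "character", zUnits = "character"),
  prototype(title = "", zUnits = "nm"))

setValidity("HeightField", function(object) {
  h <- object@heights
  if (!is.numeric(h)) return("heights must be a numeric matrix")
  if (nrow(h) < 2L || ncol(h) < 2L) return("raster must be at least 2 x 2")
  if (!all(is.finite(h))) return("all height values must be finite")
  ps <- object@pixelSize
  if (length(ps) != 2L || !all(is.finite(ps)) || any(ps <= 0))
    return("pixelSize must be two strictly positive values (x, y)")
  TRUE
})

#' Construct a HeightField
#'
#' @param heights numeric matrix of heights in nm, row-major with the top
#'   raster row first.
#' @param pixelSize pixel spacing in nm; a scalar (square pixels) or a
#'   length-2 vector \code{c(x, y)}.
#' @param title optional free-text title.
#' @param zUnits height unit string, default \code{"nm"}.
#' @return A \linkS4class{HeightField} object.
#' @examples
#' hf <- HeightField(matrix(rnorm(64), 8, 8), pixelSize = 2)
#' sq(rmsRoughness(hf))
#' @export
HeightField <- function(heights, pixelSize, title = "", zUnits = "nm") {
  if (length(pixelSize) == 1L) pixelSize <- rep(pixelSize, 2L)
  new("HeightField", heights = heights, pixelSize = as.numeric(pixelSize),
      title = title, zUnits = zUnits)
}

#' LineProfile: heights sampled along a straight line
#'
#' @slot positions distance along the line from the first endpoint (nm),
#'   monotonically increasing from 0.
#' @slot heights interpolated heights (nm).
#' @slot endpoints 2 x 2 matrix of physical (x, y) endpoints in nm.
#' @aliases LineProfile-class
#' @exportClass LineProfile
setClass("LineProfile",
  representation(positions = "numeric", heights = "numeric",
                 endpoints = "matrix"))

setValidity("LineProfile", function(object) {
  p <- object@positions
  if (length(p) != length(object@heights))
    return("positions and heights must have the same length")
  if (length(p) < 2L || p[1] != 0 || any(diff(p) <= 0))
    return("positions must increase monotonically from 0")
  d <- sqrt(sum((object@endpoints[2, ] - object@endpoints[1, ])^2))
  if (abs(p[length(p)] - d) > 1e-6 * max(1, d))
    return("positions must end at the Euclidean endpoint distance")
  TRUE
})

#' RoughnessReport: RMS roughness of a height field
#'
#' @slot sq RMS roughness Sq (nm): root mean square deviation from the mean.
#' @slot meanHeight mean height (nm).
#' @slot nPixels number of pixels that entered the statistic.
#' @aliases RoughnessReport-class
#' @exportClass RoughnessReport
setClass("RoughnessReport",
  representation(sq = "numeric", meanHeight = "numeric", nPixels = "integer"))

#' HdcfCurve: one-dimensional height-difference correlation function
#'
#' \eqn{g(r)} is the mean of \eqn{[h(x + r) - h(x)]^2} over all scan lines
#' along one raster axis and all valid origins. For a periodic surface it
#' oscillates with the surface period; for an uncorrelated surface it is flat
#' at \eqn{2 S_q^2}.
#'
#' @slot lags lag distances (nm), strictly increasing from one pixel spacing.
#' @slot g mean squared height difference at each lag (nm^2).
#' @slot axis raster axis the lags run along, \code{"x"} or \code{"y"}.
#' @slot nPairs number of pixel pairs averaged at each lag.
#' @aliases HdcfCurve-class
#' @exportClass HdcfCurve
setClass("HdcfCurve",
  representation(lags = "numeric", g = "numeric", axis = "character",
                 nPairs = "integer"))

setValidity("HdcfCurve", function(object) {
  if (length(object@lags) != length(object@g))
    return("lags and g must have equal length")
  if (any(diff(object@lags) <= 0)) return("lags must be strictly increasing")
  if (any(object@g < 0)) return("g must be non-negative")
  if (!object@axis %in% c("x", "y")) return("axis must be 'x' or 'y'")
  TRUE
})

#' RippleMetrics: periodicity and amplitude read off the HDCF
#'
#' Extracted from the first interior local maximum of \eqn{g(r)} at lag
#' \eqn{r_1}: periodicity \eqn{= 2 r_1} and peak-to-peak amplitude
#' \eqn{= \sqrt{2 g(r_1)}}, both exact for a sinusoidal surface.
#'
#' @slot periodicity ripple period (nm); NA when not detected.
#' @slot amplitudePp peak-to-peak amplitude (nm); NA when not detected.
#' @slot firstMaxLag refined lag of the first HDCF maximum (nm).
#' @slot firstMaxG g at the refined maximum (nm^2).
#' @slot detected logical flag.
#' @slot prominence relative prominence of the first maximum (0..1).
#' @slot axis raster axis of the underlying HDCF.
#' @aliases RippleMetrics-class
#' @exportClass RippleMetrics
setClass("RippleMetrics",
  representation(periodicity = "numeric", amplitudePp = "numeric",
                 firstMaxLag = "numeric", firstMaxG = "numeric",
                 detected = "logical", prominence = "numeric",
                 axis = "character"))

#' PowerSpectrum2D: centred 2D power spectrum of a height field
#'
#' @slot freqX,freqY spatial frequency axes (nm^-1), ascending, zero at the
#'   centre bin.
#' @slot power matrix of \eqn{|F|^2}, rows indexed by freqY, columns by freqX.
#' @slot window window function that was applied (\code{"hann"} or
#'   \code{"none"}).
#' @slot nPixels number of raster pixels of the source field.
#' @aliases PowerSpectrum2D-class
#' @exportClass PowerSpectrum2D
setClass("PowerSpectrum2D",
  representation(freqX = "numeric", freqY = "numeric", power = "matrix",
                 window = "character", nPixels = "integer"))

setValidity("PowerSpectrum2D", function(object) {
  if (nrow(object@power) != length(object@freqY) ||
      ncol(object@power) != length(object@freqX))
    return("power dimensions must match frequency axes")
  if (any(object@power < 0)) return("power must be non-negative")
  TRUE
})

#' GrainLabelMap: height-threshold segmentation of a field
#'
#' @slot labels integer matrix, 0 = background, 1..K = grains, numbered in
#'   raster-scan order of each grain's topmost-leftmost pixel.
#' @slot threshold height threshold (nm) that defined the foreground.
#' @slot pixelSize numeric(2), pixel spacing (x, y) in nm.
#' @slot connectivity 4 or 8.
#' @aliases GrainLabelMap-class
#' @exportClass GrainLabelMap
setClass("GrainLabelMap",
  representation(labels = "matrix", threshold = "numeric",
                 pixelSize = "numeric", connectivity = "integer"))

setValidity("GrainLabelMap", function(object) {
  L <- object@labels
  if (any(L < 0)) return("labels must be non-negative")
  if (any(L != round(L))) return("labels must be integers")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  if (object@threshold <= 0) return("threshold must be positive")
  TRUE
})

#' SceneGroundTruth: exact truth of a synthetic scene
#'
#' @slot substrateField the substrate topography alone (no aggregates,
#'   no instrument noise).
#' @slot aggregateField the aggregate contribution alone (pointwise maximum
#'   over planted aggregates).
#' @slot masks integer matrix labelling which planted aggregate owns each
#'   pixel (0 = none).
#' @slot trueVolumes zero-basis volume (nm^3) of each planted aggregate,
#'   integrated over its mask.
#' @slot surfaceParams list echoing the generating surface parameters.
#' @slot spec the SceneSpec list the scene was generated from.
#' @aliases SceneGroundTruth-class
#' @exportClass SceneGroundTruth
setClass("SceneGroundTruth",
  representation(substrateField = "HeightField",
                 aggregateField = "HeightField",
                 masks = "matrix", trueVolumes = "numeric",
                 surfaceParams = "list", spec = "list"))
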