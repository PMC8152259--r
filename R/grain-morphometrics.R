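#' Segment aggregates by height threshold
#'
#' Labels the connected components of \eqn{\{h > \mathrm{threshold}\}}.
#' Components are numbered in raster-scan order of their topmost-leftmost
#' pixel; components smaller than \code{minAreaPx} pixels are discarded.
#' 8-connectivity is the default because thin fibrils running diagonally
#' would fragment under 4-connectivity.
#'
#' @param field a levelled (and, for nanopatterned substrates,
#'   Fourier-filtered) \linkS4class{HeightField}.
#' @param threshold height threshold in nm, > 0.
#' @param connectivity 8 (default) or 4.
#' @param minAreaPx minimum component area in pixels (default 1).
#' @return a \linkS4class{GrainLabelMap}.
#' @export
markByThreshold <- function(field, threshold, connectivity = 8L,
                            minAreaPx = 1L) {
  stopifnot(is(field, "HeightField"))
  if (!is.numeric(threshold) || threshold <= 0)
    stopf("threshold must be a positive height in nm")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  mask <- field@heights > threshold
  L <- matrix(as.integer(EBImage::bwlabel(mask * 1)), nrow(mask), ncol(mask))
  if (connectivity == 8L && max(L) > 1L) L <- mergeDiagonal(L)
  L <- relabelGrains(L, minAreaPx)
  new("GrainLabelMap", labels = L, threshold = threshold,
      pixelSize = field@pixelSize, connectivity = connectivity)
}

# Union 4-connected labels that touch diagonally (EBImage::bwlabel is
# 4-connective) using a small union-find over label ids.
mergeDiagonal <- function(L) {
  nr <- nrow(L); nc <- ncol(L)
  a <- L[-nr, -nc]; b <- L[-1, -1]     # top-left vs bottom-right
  c_ <- L[-1, -nc]; d <- L[-nr, -1]    # bottom-left vs top-right
  pairs <- rbind(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
                 cbind(c_[c_ > 0 & d > 0 & c_ != d], d[c_ > 0 & d > 0 & c_ != d]))
  if (nrow(pairs) == 0L) return(L)
  parent <- seq_len(max(L))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(parent), find, integer(1))
  out <- L
  out[L > 0] <- roots[L[L > 0]]
  out
}

# Drop small components and renumber in raster-scan order of each grain's
# topmost-leftmost pixel.
relabelGrains <- function(L, minAreaPx) {
  ids <- sort(unique(L[L > 0]))
  if (length(ids) == 0L) return(L)
  areas <- tabulate(L, nbins = max(ids))[ids]
  keep <- ids[areas >= minAreaPx]
  out <- matrix(0L, nrow(L), ncol(L))
  if (length(keep) == 0L) return(out)
  # order key: topmost row first, then leftmost column within that row
  key <- vapply(keep, function(id) {
    w <- which(L == id, arr.ind = TRUE)
    top <- min(w[, 1])
    left <- min(w[w[, 1] == top, 2])
    top * (ncol(L) + 1) + left
  }, numeric(1))
  keep <- keep[order(key)]
  for (newId in seq_along(keep)) out[L == keep[newId]] <- newId
  out
}

#' Zero-basis volume of a grain
#'
#' The integral of the height above the \eqn{z = 0} basis plane over the
#' grain's pixels: \eqn{\sum h \cdot p_x p_y}. Heights are integrated from
#' zero, not from the threshold plane.
#'
#' @param field the source \linkS4class{HeightField}.
#' @param labelMap a \linkS4class{GrainLabelMap} for the same raster.
#' @param grainId grain label (1..K).
#' @return volume in nm^3.
#' @export
zeroBasisVolume <- function(field, labelMap, grainId) {
  stopifnot(is(field, "HeightField"), is(labelMap, "GrainLabelMap"))
  sel <- labelMap@labels == grainId
  if (!any(sel)) stopf("no grain with id %s", grainId)
  sum(field@heights[sel]) * prod(labelMap@pixelSize)
}

#' Projected boundary length of a grain
#'
#' Length of the marching-squares contour of the grain in physical units.
#' Each 2x2 pixel window whose corners straddle the grain mask contributes
#' one (or, for checkerboard saddles, two) straight segments joining the
#' threshold crossings on the window edges. When the source field is given,
#' the crossing position along each edge is linearly interpolated from the
#' two corner heights, so the contour of a smoothly sloped grain converges
#' to the continuum outline (a large cone-profile disk converges to
#' \eqn{2\pi R}). Without the field, crossings sit at the edge midpoints
#' (classic mid-edge marching squares): an isolated pixel then contributes
#' a diamond of length \eqn{2\sqrt{2} p} and a 2x2 grain
#' \eqn{4p + 2\sqrt{2} p}; note the mid-edge contour of a large binary disk
#' converges to about 1.05 times the true perimeter, which is why the
#' interpolating form is preferred whenever heights are available.
#'
#' Saddles are resolved consistently with 8-connected foreground (both
#' resolutions have equal mid-edge length, so the choice affects topology
#' only). Grains touching the raster border are closed along the border:
#' the mask is padded with background whose virtual height mirrors the
#' border pixel about the threshold, placing the crossing exactly on the
#' border mid-edge.
#'
#' @param labelMap a \linkS4class{GrainLabelMap}.
#' @param grainId grain label (1..K).
#' @param field optional source \linkS4class{HeightField}; when given, edge
#'   crossings are height-interpolated.
#' @return boundary length in nm.
#' @export
boundaryLength <- function(labelMap, grainId, field = NULL) {
  stopifnot(is(labelMap, "GrainLabelMap"))
  sel <- labelMap@labels == grainId
  if (!any(sel)) stopf("no grain with id %s", grainId)
  maskBoundaryLength(sel, labelMap@pixelSize,
                     heights = if (!is.null(field)) field@heights,
                     threshold = labelMap@threshold)
}

# Marching-squares contour length of a logical mask, with optional
# height-interpolated edge crossings.
maskBoundaryLength <- function(mask, ps, heights = NULL, threshold = NULL) {
  nr <- nrow(mask); nc <- ncol(mask)
  P <- matrix(FALSE, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- mask
  a <- P[-(nr + 2L), -(nc + 2L)]  # TL corner of each 2x2 window
  b <- P[-(nr + 2L), -1L]         # TR
  cc <- P[-1L, -(nc + 2L)]        # BL
  d <- P[-1L, -1L]                # BR
  code <- a + 2L * b + 4L * cc + 8L * d
  mixed <- which(code > 0L & code < 15L)
  if (length(mixed) == 0L) return(0)
  half <- rep(0.5, length(mixed))
  if (is.null(heights)) {
    fT <- fB <- fL <- fR <- half
  } else {
    # pad heights with the mirror of the border pixel about the threshold,
    # so border crossings land on the border mid-edge
    H <- matrix(threshold, nr + 2L, nc + 2L)
    H[2:(nr + 1L), 2:(nc + 1L)] <- heights
    H[1L, 2:(nc + 1L)] <- 2 * threshold - heights[1L, ]
    H[nr + 2L, 2:(nc + 1L)] <- 2 * threshold - heights[nr, ]
    H[2:(nr + 1L), 1L] <- 2 * threshold - heights[, 1L]
    H[2:(nr + 1L), nc + 2L] <- 2 * threshold - heights[, nc]
    hTL <- H[-(nr + 2L), -(nc + 2L)][mixed]
    hTR <- H[-(nr + 2L), -1L][mixed]
    hBL <- H[-1L, -(nc + 2L)][mixed]
    hBR <- H[-1L, -1L][mixed]
    frac <- function(h1, h2) {
      f <- (h1 - threshold) / (h1 - h2)
      f[!is.finite(f) | f <= 0 | f >= 1] <- 0.5
      f
    }
    fT <- frac(hTL, hTR)   # crossing x on the top edge, in units of ps[1]
    fB <- frac(hBL, hBR)
    fL <- frac(hTL, hBL)   # crossing y on the left edge, in units of ps[2]
    fR <- frac(hTR, hBR)
  }
  cw <- code[mixed]
  px <- ps[1]; py <- ps[2]
  segLT <- sqrt((fT * px)^2 + (fL * py)^2)                 # around TL
  segTR <- sqrt(((1 - fT) * px)^2 + (fR * py)^2)           # around TR
  segLB <- sqrt((fB * px)^2 + ((1 - fL) * py)^2)           # around BL
  segRB <- sqrt(((1 - fB) * px)^2 + ((1 - fR) * py)^2)     # around BR
  segLR <- sqrt(px^2 + ((fR - fL) * py)^2)                 # left to right
  segTB <- sqrt(((fB - fT) * px)^2 + py^2)                 # top to bottom
  len <- numeric(length(cw))
  len[cw == 1L | cw == 14L] <- segLT[cw == 1L | cw == 14L]
  len[cw == 2L | cw == 13L] <- segTR[cw == 2L | cw == 13L]
  len[cw == 4L | cw == 11L] <- segLB[cw == 4L | cw == 11L]
  len[cw == 8L | cw == 7L] <- segRB[cw == 8L | cw == 7L]
  len[cw == 3L | cw == 12L] <- segLR[cw == 3L | cw == 12L]
  len[cw == 5L | cw == 10L] <- segTB[cw == 5L | cw == 10L]
  sdl <- cw == 6L                       # fg TR+BL: isolate TL and BR
  len[sdl] <- segLT[sdl] + segRB[sdl]
  sdl <- cw == 9L                       # fg TL+BR: isolate TR and BL
  len[sdl] <- segTR[sdl] + segLB[sdl]
  sum(len)
}

#' Spreading coefficient of an aggregate
#'
#' The ratio of projected boundary length to zero-basis volume,
#' \eqn{L/V} in nm^-2. Large values indicate frayed, extended aggregates
#' (e.g. radial fibrils), small values compact particle-like ones. Under a
#' lateral magnification by \eqn{s}, \eqn{L} scales by \eqn{s} and \eqn{V}
#' by \eqn{s^2}, so the coefficient scales by \eqn{1/s}.
#'
#' @param volume zero-basis volume (nm^3), > 0.
#' @param boundaryLen projected boundary length (nm).
#' @return spreading coefficient (nm^-2).
#' @export
spreadingCoefficient <- function(volume, boundaryLen) {
  if (any(volume <= 0)) stopf("volume must be positive")
  boundaryLen / volume
}

#' Per-grain morphometrics table
#'
#' Computes, for every grain in a label map, the projected area, zero-basis
#' volume, boundary length, spreading coefficient, maximum height, centroid
#' and a border flag (TRUE when the grain touches the raster border).
#'
#' @param field the source \linkS4class{HeightField}.
#' @param labelMap a \linkS4class{GrainLabelMap} for the same raster.
#' @return data.frame with one row per grain: \code{grainId},
#'   \code{areaNm2}, \code{volumeNm3}, \code{boundaryNm},
#'   \code{spreadingPerNm2}, \code{maxHeightNm}, \code{centroidXNm},
#'   \code{centroidYNm}, \code{borderFlag}.
#' @export
grainSummary <- function(field, labelMap) {
  stopifnot(is(field, "HeightField"), is(labelMap, "GrainLabelMap"))
  L <- labelMap@labels
  K <- max(L)
  ps <- labelMap@pixelSize
  pA <- prod(ps)
  if (K == 0L)
    return(data.frame(grainId = integer(0), areaNm2 = numeric(0),
                      volumeNm3 = numeric(0), boundaryNm = numeric(0),
                      spreadingPerNm2 = numeric(0), maxHeightNm = numeric(0),
                      centroidXNm = numeric(0), centroidYNm = numeric(0),
                      borderFlag = logical(0)))
  h <- field@heights
  idx <- which(L > 0)
  lab <- L[idx]
  rows <- (idx - 1L) %% nrow(L) + 1L
  cols <- (idx - 1L) %/% nrow(L) + 1L
  area <- tabulate(lab, K) * pA
  vol <- as.numeric(tapply(h[idx], lab, sum)) * pA
  maxH <- as.numeric(tapply(h[idx], lab, max))
  cx <- as.numeric(tapply((cols - 1) * ps[1], lab, mean))
  cy <- as.numeric(tapply((rows - 1) * ps[2], lab, mean))
  border <- as.logical(tapply(rows == 1L | rows == nrow(L) |
                              cols == 1L | cols == ncol(L), lab, any))
  bl <- vapply(seq_len(K), function(id)
    maskBoundaryLength(L == id, ps, heights = h,
                       threshold = labelMap@threshold), numeric(1))
  data.frame(grainId = seq_len(K), areaNm2 = area, volumeNm3 = vol,
             boundaryNm = bl, spreadingPerNm2 = bl / vol,
             maxHeightNm = maxH, centroidXNm = cx, centroidYNm = cy,
             borderFlag = border)
}

#' Rule-based artefact exclusion
#'
#' Replaces the manual curation of segmentation artefacts (substrate
#' features crossing the threshold, isolated pixels) with deterministic,
#' declarative rules. Rules are applied in order: explicit \code{drop} ids,
#' \code{minArea} (nm^2), \code{minMaxHeight} (nm), exclusion regions
#' (rectangles in physical coordinates, matched against grain centroids);
#' explicit \code{keep} ids override every removal. A grain id in both
#' \code{keep} and \code{drop} is a configuration error.
#'
#' @param morphometrics data.frame from \code{\link{grainSummary}}.
#' @param rules list with any of \code{minArea}, \code{minMaxHeight},
#'   \code{excludeRegions} (data.frame xmin, xmax, ymin, ymax in nm),
#'   \code{keep}, \code{drop} (integer grain ids).
#' @return the input data.frame with logical \code{keptFlag} and character
#'   \code{rule} columns recording which rule removed each grain.
#' @export
excludeArtefacts <- function(morphometrics, rules = list()) {
  m <- morphometrics
  keepIds <- as.integer(rules$keep %||% integer(0))
  dropIds <- as.integer(rules$drop %||% integer(0))
  clash <- intersect(keepIds, dropIds)
  if (length(clash) > 0L)
    stopf("grain id(s) %s in both keep and drop lists",
          paste(clash, collapse = ", "))
  kept <- rep(TRUE, nrow(m))
  rule <- rep("", nrow(m))
  mark <- function(sel, name) {
    sel <- sel & kept
    kept[sel] <<- FALSE
    rule[sel] <<- name
  }
  mark(m$grainId %in% dropIds, "drop_list")
  if (!is.null(rules$minArea)) mark(m$areaNm2 < rules$minArea, "min_area")
  if (!is.null(rules$minMaxHeight))
    mark(m$maxHeightNm < rules$minMaxHeight, "min_max_height")
  if (!is.null(rules$excludeRegions)) {
    rg <- rules$excludeRegions
    for (k in seq_len(nrow(rg))) {
      inside <- m$centroidXNm >= rg$xmin[k] & m$centroidXNm <= rg$xmax[k] &
                m$centroidYNm >= rg$ymin[k] & m$centroidYNm <= rg$ymax[k]
      mark(inside, "exclude_region")
    }
  }
  forced <- m$grainId %in% keepIds & !kept
  kept[forced] <- TRUE
  rule[forced] <- ""
  m$keptFlag <- kept
  m$rule <- rule
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reproducible default height threshold
#'
#' Background mean plus \code{k} background standard deviations, a
#' scriptable stand-in for the per-image manual threshold choice: it covers
#' the topographic background while keeping aggregates. Both background
#' statistics are estimated robustly (median and MAD) so that the
#' aggregates themselves, which can dominate the plain mean and Sq of an
#' image, do not inflate the threshold. The default \code{k = 5} clears a
#' Gaussian background with large margin.
#'
#' @param field a levelled (and filtered) \linkS4class{HeightField}.
#' @param k multiple of the background standard deviation (default 5).
#' @return threshold in nm.
#' @export
autoThreshold <- function(field, k = 5) {
  h <- field@heights
  median(h) + k * mad(h)
}
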