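#' RMS surface roughness Sq
#'
#' \eqn{S_q} is the root mean square deviation of the heights from their
#' mean. Invariant under adding a constant and under raster rotation.
#'
#' @param field a levelled \linkS4class{HeightField}.
#' @return a \linkS4class{RoughnessReport}.
#' @export
rmsRoughness <- function(field) {
  stopifnot(is(field, "HeightField"))
  h <- field@heights
  m <- mean(h)
  new("RoughnessReport", sq = sqrt(mean((h - m)^2)), meanHeight = m,
      nPixels = length(h))
}

#' One-dimensional height-difference correlation function
#'
#' \eqn{g(r) = \langle [h(x + r) - h(x)]^2 \rangle}, averaged over all scan
#' lines along one raster axis and all valid origins. Lags run from one
#' pixel spacing to half the raster extent. For an uncorrelated surface
#' \eqn{g} plateaus at \eqn{2 S_q^2}; for a sinusoid of peak-to-peak
#' amplitude \eqn{A} and wavelength \eqn{\lambda},
#' \eqn{g(r) = (A^2/4)(1 - \cos 2\pi r/\lambda)}.
#'
#' @param field a levelled \linkS4class{HeightField}.
#' @param axis \code{"x"} (lags along the rows, default) or \code{"y"}.
#' @param maxLag optional maximum lag in pixels (default: half the extent).
#' @return an \linkS4class{HdcfCurve}.
#' @export
hdcf1D <- function(field, axis = c("x", "y"), maxLag = NULL) {
  stopifnot(is(field, "HeightField"))
  axis <- match.arg(axis)
  M <- if (axis == "x") field@heights else t(field@heights)
  px <- if (axis == "x") field@pixelSize[1] else field@pixelSize[2]
  n <- ncol(M)
  L <- if (is.null(maxLag)) n %/% 2L else min(as.integer(maxLag), n - 1L)
  if (L < 8L) stopf("raster too small for an HDCF: only %d lags available", L)
  g <- numeric(L)
  np <- integer(L)
  for (d in seq_len(L)) {
    diffs <- M[, (1L + d):n, drop = FALSE] - M[, seq_len(n - d), drop = FALSE]
    g[d] <- mean(diffs * diffs)
    np[d] <- length(diffs)
  }
  new("HdcfCurve", lags = seq_len(L) * px, g = g, axis = axis, nPairs = np)
}

#' Ripple periodicity and amplitude from an HDCF curve
#'
#' Locates the first interior local maximum of \eqn{g(r)} at lag \eqn{r_1}
#' (with parabolic sub-pixel refinement over the three samples around the
#' discrete maximum) and reports periodicity \eqn{= 2 r_1} and peak-to-peak
#' amplitude \eqn{= \sqrt{2 g(r_1)}} -- both exact for a sinusoidal surface,
#' where the first maximum sits at half the wavelength and
#' \eqn{g(\lambda/2) = A^2/2}. Detection fails (without error) when no
#' interior local maximum exists, or when its prominence, measured as
#' \eqn{(g(r_1) - \min_{r \le r_1} g)/g(r_1)}, is below
#' \code{prominenceThreshold} (an uncorrelated surface has a flat \eqn{g}
#' and prominence near zero), or when \eqn{g} fails to dip again after the
#' maximum by at least the same relative amount -- a genuine periodic
#' modulation oscillates, whereas the \eqn{g} of smooth long-range
#' roughness merely rises to its plateau, where small sampling bumps would
#' otherwise mimic a very prominent first maximum.
#'
#' @param curve an \linkS4class{HdcfCurve} with at least 8 lags.
#' @param prominenceThreshold minimum relative prominence (default 0.2).
#' @return a \linkS4class{RippleMetrics}.
#' @export
rippleMetricsFromHdcf <- function(curve, prominenceThreshold = 0.2) {
  stopifnot(is(curve, "HdcfCurve"))
  g <- curve@g
  lags <- curve@lags
  L <- length(g)
  if (L < 8L) stopf("HDCF curve must have at least 8 lags")
  none <- new("RippleMetrics", periodicity = NA_real_, amplitudePp = NA_real_,
              firstMaxLag = NA_real_, firstMaxG = NA_real_, detected = FALSE,
              prominence = 0, axis = curve@axis)
  i <- NA_integer_
  for (k in 2:(L - 1L)) {
    if (g[k] > g[k - 1L] && g[k] >= g[k + 1L]) { i <- k; break }
  }
  if (is.na(i)) return(none)
  prom <- (g[i] - min(g[seq_len(i)])) / g[i]
  if (!is.finite(prom) || prom < prominenceThreshold) {
    none@prominence <- max(0, prom)
    return(none)
  }
  # oscillation check: g must fall again after the maximum (the first
  # minimum of a sinusoid sits near lag = 2 r1)
  upper <- min(3L * i, L)
  dip <- (g[i] - min(g[i:upper])) / g[i]
  if (!is.finite(dip) || dip < prominenceThreshold) {
    none@prominence <- max(0, prom)
    return(none)
  }
  denom <- g[i - 1L] - 2 * g[i] + g[i + 1L]
  delta <- if (denom != 0) 0.5 * (g[i - 1L] - g[i + 1L]) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  dlag <- lags[2L] - lags[1L]
  r1 <- lags[i] + delta * dlag
  gmax <- g[i] - 0.25 * (g[i - 1L] - g[i + 1L]) * delta
  new("RippleMetrics", periodicity = 2 * r1, amplitudePp = sqrt(2 * gmax),
      firstMaxLag = r1, firstMaxG = gmax, detected = TRUE, prominence = prom,
      axis = curve@axis)
}

#' Ripple metrics of a field with automatic axis selection
#'
#' Computes the HDCF along both raster axes and keeps the axis with the more
#' prominent first maximum, i.e. the axis along the ripple wave vector.
#'
#' @param field a levelled \linkS4class{HeightField}.
#' @param prominenceThreshold passed to \code{\link{rippleMetricsFromHdcf}}.
#' @return a \linkS4class{RippleMetrics}.
#' @export
rippleMetrics <- function(field, prominenceThreshold = 0.2) {
  mx <- rippleMetricsFromHdcf(hdcf1D(field, "x"), prominenceThreshold)
  my <- rippleMetricsFromHdcf(hdcf1D(field, "y"), prominenceThreshold)
  if (my@detected && (!mx@detected || my@prominence > mx@prominence)) my else mx
}

#' Export an HDCF curve as CSV
#'
#' Columns \code{lag_nm}, \code{g_nm2}, \code{n_pairs}.
#' @param curve an \linkS4class{HdcfCurve}.
#' @param path destination CSV path.
#' @export
writeHdcfCSV <- function(curve, path) {
  stopifnot(is(curve, "HdcfCurve"))
  utils::write.csv(data.frame(lag_nm = curve@lags, g_nm2 = curve@g,
                              n_pairs = curve@nPairs),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Centred 2D power spectrum of a height field
#'
#' Removes the mean, applies a separable periodic Hann window (or none) and
#' returns the centred magnitude-squared 2D DFT with physical frequency axes
#' \eqn{f = k/(n \cdot \mathrm{pixel size})}. Without a window, Parseval's
#' identity holds: \code{sum(power)/nPixels^2} equals the field variance.
#'
#' @param field a levelled \linkS4class{HeightField}.
#' @param window \code{"hann"} (default) or \code{"none"}.
#' @return a \linkS4class{PowerSpectrum2D}.
#' @export
fftPower2D <- function(field, window = c("hann", "none")) {
  stopifnot(is(field, "HeightField"))
  window <- match.arg(window)
  h <- field@heights
  h <- h - mean(h)
  nr <- nrow(h); nc <- ncol(h)
  if (window == "hann") {
    wr <- 0.5 * (1 - cos(2 * pi * (0:(nr - 1)) / nr))
    wc <- 0.5 * (1 - cos(2 * pi * (0:(nc - 1)) / nc))
    h <- h * outer(wr, wc)
  }
  F <- stats::fft(h)
  pw <- Mod(F)^2
  fy <- fftFreq(nr, field@pixelSize[2])
  fx <- fftFreq(nc, field@pixelSize[1])
  oy <- order(fy); ox <- order(fx)
  new("PowerSpectrum2D", freqX = fx[ox], freqY = fy[oy],
      power = pw[oy, ox, drop = FALSE], window = window,
      nPixels = length(h))
}

#' Detect anisotropy peaks in a 2D power spectrum
#'
#' Finds off-DC local maxima whose power exceeds
#' \code{prominenceThreshold} times the median power in their frequency
#' annulus (all bins at the same \eqn{|f|}), excluding the DC bin and its
#' \code{dcExcludeBins} neighbourhood where long-range roughness
#' concentrates. Because the source field is real, the spectrum is point
#' symmetric and every peak has an exact mirror at \eqn{-f}; one
#' representative per pair is returned (the half-plane with
#' \eqn{f_x > 0}, or \eqn{f_x = 0, f_y > 0}).
#'
#' The annulus-relative prominence makes detection scale free: for a
#' featureless (isotropic) spectrum the largest power/median ratio over a
#' raster of this size stays well below the default threshold, while a
#' coherent ripple concentrates orders of magnitude more power into a few
#' bins.
#'
#' @param spectrum a \linkS4class{PowerSpectrum2D}.
#' @param prominenceThreshold minimum power/annulus-median ratio (default 30).
#' @param dcExcludeBins radius (in frequency bins) of the excluded DC
#'   neighbourhood (default 3).
#' @param relPowerFloor a peak must also carry at least this fraction of the
#'   strongest off-DC bin's power (default 1e-4); this discards numerically
#'   empty bins that only look prominent because their annulus is empty too
#'   (e.g. leakage residue of a noiseless synthetic surface).
#' @param scanAxisExcludeBins residual scan-line offsets put power on the
#'   \eqn{f_x = 0} column (features constant along the fast-scan axis);
#'   candidates within this many bins of that column are excluded
#'   (default 2). Set to 0 to detect ripples with a wave vector along y.
#' @return data.frame with columns \code{fx}, \code{fy} (nm^-1),
#'   \code{freqMag}, \code{power}, \code{prominence}; zero rows when the
#'   spectrum is isotropic.
#' @export
detectAnisotropyPeaks <- function(spectrum, prominenceThreshold = 30,
                                  dcExcludeBins = 3, relPowerFloor = 1e-4,
                                  scanAxisExcludeBins = 2) {
  stopifnot(is(spectrum, "PowerSpectrum2D"))
  pw <- spectrum@power
  fx <- spectrum@freqX; fy <- spectrum@freqY
  FX <- matrix(fx, nrow(pw), ncol(pw), byrow = TRUE)
  FY <- matrix(fy, nrow(pw), ncol(pw))
  rho <- sqrt(FX^2 + FY^2)
  df <- min(diff(sort(fx))[1], diff(sort(fy))[1])
  ann <- as.integer(round(rho / df))
  annMed <- tapply(as.vector(pw), as.vector(ann), median)
  medOf <- annMed[as.character(ann)]
  prom <- pw / (matrix(medOf, nrow(pw), ncol(pw)) + 1e-300)
  # strict local maxima over the 8-neighbourhood (borders excluded)
  nr <- nrow(pw); nc <- ncol(pw)
  isMax <- matrix(FALSE, nr, nc)
  ci <- 2:(nr - 1); cj <- 2:(nc - 1)
  centre <- pw[ci, cj]
  isMax[ci, cj] <-
    centre >= pw[ci - 1, cj] & centre >= pw[ci + 1, cj] &
    centre >= pw[ci, cj - 1] & centre >= pw[ci, cj + 1] &
    centre >= pw[ci - 1, cj - 1] & centre >= pw[ci - 1, cj + 1] &
    centre >= pw[ci + 1, cj - 1] & centre >= pw[ci + 1, cj + 1] &
    (centre > pw[ci - 1, cj] | centre > pw[ci + 1, cj] |
     centre > pw[ci, cj - 1] | centre > pw[ci, cj + 1])
  offDc <- ann > dcExcludeBins
  maxOffDc <- max(pw[offDc])
  dfx <- diff(sort(fx))[1]
  sel <- isMax & offDc & prom >= prominenceThreshold &
    pw >= relPowerFloor * maxOffDc &
    (scanAxisExcludeBins == 0 | abs(FX) > (scanAxisExcludeBins + 0.5) * dfx) &
    (FX > 0 | (FX == 0 & FY > 0))
  idx <- which(sel)
  out <- data.frame(fx = FX[idx], fy = FY[idx], freqMag = rho[idx],
                    power = pw[idx], prominence = prom[idx])
  out[order(-out$prominence), , drop = FALSE]
}
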