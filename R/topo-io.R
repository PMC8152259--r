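GSF_MAGIC <- "Gwyddion Simple Field 1.0"

#' Read a Gwyddion Simple Field (.gsf) file
#'
#' GSF is the minimal single-channel raster interchange format of the
#' Gwyddion SPM software: a text header followed by NUL padding to a 4-byte
#' boundary and a row-major little-endian float32 payload (top raster row
#' first). Physical sizes are taken from the XReal/YReal header fields;
#' lateral and height units default to nm, and values recorded in metres
#' (\code{XYUnits = "m"} / \code{ZUnits = "m"}) are converted to nm.
#'
#' @param path path to the .gsf file.
#' @return A \linkS4class{HeightField} with heights in nm.
#' @seealso \code{\link{writeGSF}}
#' @export
readGSF <- function(path) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  raw <- readBin(path, "raw", n = file.size(path))
  nul <- which(raw == as.raw(0L))
  if (length(nul) == 0L) stopf("not a GSF file (no header terminator): %s", path)
  headerText <- rawToChar(raw[seq_len(nul[1] - 1L)])
  lines <- strsplit(headerText, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 1L || lines[1] != GSF_MAGIC)
    stopf("not a GSF file (bad magic line): %s", path)
  kv <- list()
  for (ln in lines[-1]) {
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stopf("malformed GSF header line: %s", ln)
    kv[[m[2]]] <- m[3]
  }
  need <- c("XRes", "YRes", "XReal", "YReal")
  if (!all(need %in% names(kv)))
    stopf("GSF header missing required fields: %s",
          paste(setdiff(need, names(kv)), collapse = ", "))
  xres <- as.integer(kv$XRes); yres <- as.integer(kv$YRes)
  xreal <- as.numeric(kv$XReal); yreal <- as.numeric(kv$YReal)
  xyUnits <- if (is.null(kv$XYUnits)) "nm" else kv$XYUnits
  zUnits <- if (is.null(kv$ZUnits)) "nm" else kv$ZUnits
  if (xyUnits == "m") { xreal <- xreal * 1e9; yreal <- yreal * 1e9 }
  dataStart <- 4L * as.integer(ceiling(nul[1] / 4)) + 1L
  npix <- xres * yres
  payload <- raw[dataStart:length(raw)]
  if (length(payload) != 4L * npix)
    stopf("GSF payload size mismatch: expected %d bytes, found %d",
          4L * npix, length(payload))
  vals <- readBin(payload, "numeric", n = npix, size = 4L, endian = "little")
  if (zUnits == "m") { vals <- vals * 1e9; zUnits <- "nm" }
  if (!all(is.finite(vals))) stopf("GSF payload contains non-finite heights")
  HeightField(matrix(vals, nrow = yres, ncol = xres, byrow = TRUE),
              pixelSize = c(xreal / xres, yreal / yres),
              title = if (is.null(kv$Title)) "" else kv$Title,
              zUnits = zUnits)
}

#' Write a Gwyddion Simple Field (.gsf) file
#'
#' Writes the dialect read by \code{\link{readGSF}}: text header (XRes, YRes,
#' XReal, YReal, XYUnits, ZUnits, Title), NUL padding to a 4-byte boundary,
#' then the heights as row-major little-endian float32, top row first.
#' Heights are truncated to float32; a write/read/write cycle is
#' byte-identical.
#'
#' @param field a \linkS4class{HeightField}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeGSF <- function(field, path) {
  stopifnot(is(field, "HeightField"))
  validObject(field)
  h <- field@heights
  header <- paste0(
    GSF_MAGIC, "\n",
    "XRes = ", ncol(h), "\n",
    "YRes = ", nrow(h), "\n",
    "XReal = ", sprintf("%.17g", ncol(h) * field@pixelSize[1]), "\n",
    "YReal = ", sprintf("%.17g", nrow(h) * field@pixelSize[2]), "\n",
    "XYUnits = nm\n",
    "ZUnits = ", field@zUnits, "\n",
    if (nzchar(field@title)) paste0("Title = ", field@title, "\n") else "")
  hraw <- charToRaw(header)
  npad <- 4L - (length(hraw) %% 4L)   # 1..4 NULs, always at least one
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hraw, con)
  writeBin(raw(npad), con)
  writeBin(as.numeric(t(h)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read/write plain-text ASCII height grids
#'
#' A whitespace-separated numeric matrix, one raster row per line; lines
#' starting with \code{#} are comments. Values round-trip to at least 12
#' significant digits.
#'
#' @param path file path.
#' @param pixelSize pixel spacing in nm (scalar or \code{c(x, y)}).
#' @return \code{readASCIIGrid}: a \linkS4class{HeightField}.
#' @export
readASCIIGrid <- function(path, pixelSize) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stopf("ASCII grid needs at least 2 rows")
  rows <- lapply(strsplit(trimws(lines), "\\s+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v)) stopf("non-numeric token in ASCII grid: %s",
                        tok[which(is.na(v))[1]])
    v
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stopf("ragged rows in ASCII grid (row lengths %s)",
          paste(unique(ncols), collapse = ", "))
  HeightField(do.call(rbind, rows), pixelSize = pixelSize)
}

#' @param field a \linkS4class{HeightField} to write.
#' @rdname readASCIIGrid
#' @export
writeASCIIGrid <- function(field, path) {
  stopifnot(is(field, "HeightField"))
  validObject(field)
  lines <- apply(field@heights, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Level a height field by least-squares plane subtraction
#'
#' Fits \eqn{h = a + b x + c y} by least squares and subtracts it, removing
#' sample tilt. The output has zero mean (over the included pixels when a
#' mask is given). Idempotent.
#'
#' When protrusions such as aggregates cover a noticeable area, fitting the
#' plane through all pixels drags the zero plane up into the deposits and
#' biases zero-basis volumes; pass \code{mask} (or use
#' \code{\link{levelField}}) to fit the plane through background pixels
#' only while still subtracting it everywhere.
#'
#' @param field a \linkS4class{HeightField}.
#' @param mask optional logical matrix: pixels to include in the fit
#'   (the plane is subtracted from all pixels).
#' @return the levelled \linkS4class{HeightField}.
#' @export
planeLevel <- function(field, mask = NULL) {
  stopifnot(is(field, "HeightField"))
  h <- field@heights
  nr <- nrow(h); nc <- ncol(h)
  xc <- ((seq_len(nc) - 1) - (nc - 1) / 2) * field@pixelSize[1]
  yc <- ((seq_len(nr) - 1) - (nr - 1) / 2) * field@pixelSize[2]
  if (is.null(mask)) {
    hc <- h - mean(h)
    # centred x and y are orthogonal on the grid, so the fit separates
    bx <- sum(colSums(hc) * xc) / (nr * sum(xc^2))
    by <- sum(rowSums(hc) * yc) / (nc * sum(yc^2))
    out <- hc - outer(rep(1, nr), xc * bx) - outer(yc * by, rep(1, nc))
  } else {
    X <- matrix(xc, nr, nc, byrow = TRUE)
    Y <- matrix(yc, nr, nc)
    A <- cbind(1, X[mask], Y[mask])
    beta <- qr.coef(qr(A), h[mask])
    out <- h - beta[1] - beta[2] * X - beta[3] * Y
  }
  HeightField(out, field@pixelSize, field@title, field@zUnits)
}

#' Robust background flattening
#'
#' The flattening chain applied before any quantitative analysis: plane
#' levelling, a second plane fit restricted to background pixels (heights
#' below the background median plus \code{k} robust standard deviations,
#' i.e. aggregates are excluded from the fit), median line levelling, and a
#' final shift putting the background median at zero -- the reference plane
#' zero-basis volumes are integrated from.
#'
#' @param field a \linkS4class{HeightField}.
#' @param k background cut in robust standard deviations (default 3).
#' @return the flattened \linkS4class{HeightField}.
#' @export
levelField <- function(field, k = 3) {
  f <- planeLevel(field)
  h <- f@heights
  bg <- h < median(h) + k * mad(h)
  f <- planeLevel(f, mask = bg)
  f <- lineLevelMedian(f, mask = bg)
  out <- f@heights - median(f@heights)
  HeightField(out, field@pixelSize, field@title, field@zUnits)
}

#' Direct per-row offset polish
#'
#' Subtracts each scan line's background median directly (no cumulative
#' differences, so estimation errors do not integrate into a slow drift
#' down the image) and re-zeroes the background median. Only valid on a
#' field whose background is flat along the fast-scan axis -- i.e. after
#' any periodic ripple has been removed; on a rippled image the per-row
#' medians would sample the ripple over different column subsets and
#' inject spurious offsets. \code{\link{analyzeField}} therefore applies
#' it after Fourier filtering.
#'
#' @param field a levelled, ripple-free \linkS4class{HeightField}.
#' @param k background cut in robust standard deviations (default 3).
#' @return the polished \linkS4class{HeightField}.
#' @export
polishRowOffsets <- function(field, k = 3) {
  h <- field@heights
  bg <- h < median(h) + k * mad(h)
  off <- vapply(seq_len(nrow(h)), function(i) {
    ok <- bg[i, ]
    if (sum(ok) >= 16L) median(h[i, ok]) else NA_real_
  }, numeric(1))
  off[is.na(off)] <- 0
  h <- h - off + mean(off)
  HeightField(h - median(h), field@pixelSize, field@title, field@zUnits)
}

#' Remove scan-line offsets by median line levelling
#'
#' Estimates each scan line's offset as the cumulative sum of the medians of
#' row-to-row height differences and subtracts it, preserving the overall
#' mean. The median makes the estimate robust to aggregates crossing a
#' subset of columns; for features that span most of a scan line (a
#' near-horizontal fibril), pass a background \code{mask} so the medians
#' are taken over background columns only. Idempotent.
#'
#' @param field a \linkS4class{HeightField}.
#' @param mask optional logical matrix of background pixels; the median of
#'   each row pair is computed over columns that are background in both
#'   rows (all columns when fewer than 16 qualify).
#' @return the levelled \linkS4class{HeightField}.
#' @export
lineLevelMedian <- function(field, mask = NULL) {
  stopifnot(is(field, "HeightField"))
  h <- field@heights
  nr <- nrow(h)
  med <- vapply(seq_len(nr - 1L), function(i) {
    d <- h[i + 1L, ] - h[i, ]
    if (!is.null(mask)) {
      ok <- mask[i + 1L, ] & mask[i, ]
      if (sum(ok) >= 16L) d <- d[ok]
    }
    median(d)
  }, numeric(1))
  off <- c(0, cumsum(med))
  out <- h - off + mean(off)
  HeightField(out, field@pixelSize, field@title, field@zUnits)
}

#' Extract a height profile along a straight line
#'
#' Samples the field by bilinear interpolation at \code{nSamples} evenly
#' spaced points from \code{p0} to \code{p1} (physical (x, y) coordinates in
#' nm). Integer-coordinate samples along a raster row reproduce stored
#' values exactly.
#'
#' @param field a \linkS4class{HeightField}.
#' @param p0,p1 numeric(2) physical endpoints \code{c(x, y)} in nm.
#' @param nSamples number of samples, >= 2.
#' @return a \linkS4class{LineProfile}.
#' @export
extractProfile <- function(field, p0, p1, nSamples = 256L) {
  stopifnot(is(field, "HeightField"))
  h <- field@heights
  nr <- nrow(h); nc <- ncol(h)
  ps <- field@pixelSize
  xmax <- (nc - 1) * ps[1]; ymax <- (nr - 1) * ps[2]
  for (p in list(p0, p1)) {
    if (length(p) != 2L || p[1] < 0 || p[1] > xmax || p[2] < 0 || p[2] > ymax)
      stopf("profile endpoint (%.4g, %.4g) outside the raster [0, %.4g] x [0, %.4g] nm",
            p[1], p[2], xmax, ymax)
  }
  dist <- sqrt(sum((p1 - p0)^2))
  if (dist == 0) stopf("profile endpoints coincide")
  if (nSamples < 2L) stopf("nSamples must be at least 2")
  t <- seq(0, 1, length.out = nSamples)
  xs <- p0[1] + t * (p1[1] - p0[1])
  ys <- p0[2] + t * (p1[2] - p0[2])
  cx <- pmin(pmax(xs / ps[1], 0), nc - 1)
  cy <- pmin(pmax(ys / ps[2], 0), nr - 1)
  j0 <- pmin(floor(cx), nc - 2); i0 <- pmin(floor(cy), nr - 2)
  fx <- cx - j0; fy <- cy - i0
  idx <- function(i, j) h[cbind(i + 1L, j + 1L)]
  hh <- (1 - fx) * (1 - fy) * idx(i0, j0) + fx * (1 - fy) * idx(i0, j0 + 1) +
        (1 - fx) * fy * idx(i0 + 1, j0) + fx * fy * idx(i0 + 1, j0 + 1)
  new("LineProfile", positions = t * dist, heights = hh,
      endpoints = rbind(p0, p1))
}

#' Export a line profile as CSV
#'
#' Columns \code{position_nm}, \code{height_nm}.
#'
#' @param profile a \linkS4class{LineProfile}.
#' @param path destination CSV path.
#' @export
writeProfileCSV <- function(profile, path) {
  stopifnot(is(profile, "LineProfile"))
  utils::write.csv(data.frame(position_nm = profile@positions,
                              height_nm = profile@heights),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
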