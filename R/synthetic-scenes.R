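#' Generate a quasi-sinusoidal ripple surface
#'
#' \eqn{h(x) = (A_{pp}/2) \sin(2\pi \phi(x))} with the phase advancing by
#' \code{pixel / wavelength_local} per pixel. With \code{jitterSd = 0} the
#' surface is a pure sinusoid. Wavelength jitter is phase diffusion: the
#' local wavelength varies smoothly (Gaussian-smoothed noise, kernel width
#' one wavelength) with standard deviation \code{jitterSd} around
#' \code{wavelength}, reproducing the quasi-sinusoidal character and period
#' spread of ion-beam ripple patterns. The field has zero mean.
#'
#' @param nrow,ncol raster size in pixels.
#' @param pixelSize pixel spacing in nm (square pixels).
#' @param wavelength ripple wavelength in nm; must exceed 2 pixels (Nyquist).
#' @param amplitudePp peak-to-peak amplitude in nm.
#' @param jitterSd standard deviation of the local wavelength (nm).
#' @param axis axis along the ripple wave vector: \code{"x"} (heights vary
#'   along columns, crests vertical) or \code{"y"}.
#' @param seed optional RNG seed (only consumed when \code{jitterSd > 0}).
#' @return a \linkS4class{HeightField}.
#' @export
genRipple <- function(nrow, ncol, pixelSize, wavelength, amplitudePp,
                      jitterSd = 0, axis = c("x", "y"), seed = NULL) {
  axis <- match.arg(axis)
  if (wavelength <= 2 * pixelSize)
    stopf("wavelength %.3g nm is at or below the Nyquist limit (2 px = %.3g nm)",
          wavelength, 2 * pixelSize)
  if (amplitudePp <= 0) stopf("amplitudePp must be positive")
  n <- if (axis == "x") ncol else nrow
  gen <- function() {
    if (jitterSd > 0) {
      noise <- rnorm(n)
      kw <- max(1, round(wavelength / pixelSize))
      kern <- exp(-0.5 * ((-3 * kw):(3 * kw) / kw)^2)
      sm <- stats::filter(c(rev(noise[seq_len(3 * kw)]), noise,
                            rev(noise[(n - 3 * kw + 1):n])),
                          kern / sum(kern), sides = 2)
      sm <- as.numeric(sm[(3 * kw + 1):(3 * kw + n)])
      sm <- sm / sd(sm)
      lamLocal <- pmax(wavelength + jitterSd * sm, 2.5 * pixelSize)
      phase <- cumsum(pixelSize / lamLocal) + runif(1)
    } else {
      phase <- (0:(n - 1)) * pixelSize / wavelength
    }
    (amplitudePp / 2) * sin(2 * pi * phase)
  }
  prof <- withSeed(seed, gen())
  prof <- prof - mean(prof)
  h <- if (axis == "x") matrix(prof, nrow, ncol, byrow = TRUE)
       else matrix(prof, nrow, ncol)
  HeightField(h, pixelSize, title = "synthetic ripple")
}

#' Generate isotropic long-range roughness
#'
#' A random field with Gaussian autocorrelation
#' \eqn{C(r) = \sigma^2 e^{-r^2 / 2\ell^2}}, synthesized spectrally by
#' random-phase synthesis: deterministic spectral amplitudes proportional
#' to the square root of the power spectrum
#' \eqn{\propto e^{-2\pi^2 \ell^2 |f|^2}} with uniform phases
#' (antisymmetrized so the field is exactly real). The heights are
#' asymptotically Gaussian by superposition. Because the amplitudes are
#' deterministic, every sample attains the target roughness exactly
#' (Parseval), which keeps the planted Sq an exact ground truth even when
#' the correlation length is a sizeable fraction of the raster; the DC bin
#' is zeroed, so every sample also has exactly zero mean.
#'
#' @param nrow,ncol raster size in pixels.
#' @param pixelSize pixel spacing in nm.
#' @param rms target ensemble RMS roughness (nm); 0 gives a zero field.
#' @param corrLength correlation length \eqn{\ell} in nm (> pixel size).
#' @param seed optional RNG seed.
#' @return a \linkS4class{HeightField}.
#' @export
genLongRangeRoughness <- function(nrow, ncol, pixelSize, rms, corrLength,
                                  seed = NULL) {
  if (rms < 0) stopf("rms must be non-negative")
  if (rms == 0)
    return(HeightField(matrix(0, nrow, ncol), pixelSize,
                       title = "long-range roughness"))
  if (corrLength <= pixelSize)
    stopf("corrLength must exceed the pixel size")
  fx <- fftFreq(ncol, pixelSize)
  fy <- fftFreq(nrow, pixelSize)
  rho2 <- outer(fy^2, fx^2, `+`)
  A <- exp(-pi^2 * corrLength^2 * rho2)
  A[1, 1] <- 0
  A <- A * rms * (nrow * ncol) / sqrt(sum(A^2))
  Phi <- withSeed(seed, matrix(runif(nrow * ncol, 0, 2 * pi), nrow, ncol))
  # antisymmetrize the phases (phi(-k) = -phi(k)) so the spectrum is
  # Hermitian and the synthesized field exactly real
  revIdx <- function(n) c(1L, n:2L)
  Phi <- Phi - Phi[revIdx(nrow), revIdx(ncol)]   # uniform marginals, odd in k
  h <- Re(stats::fft(A * exp(1i * Phi), inverse = TRUE)) / (nrow * ncol)
  HeightField(h, pixelSize, title = "long-range roughness")
}

#' Generate an amorphous-aggregate blob
#'
#' An isotropic Gaussian bump \eqn{H e^{-r^2 / 2\sigma^2}} centred at a
#' physical (x, y) position, modelling a compact amorphous deposit.
#'
#' @param nrow,ncol raster size in pixels.
#' @param pixelSize pixel spacing in nm.
#' @param center numeric(2) physical centre \code{c(x, y)} in nm.
#' @param height peak height \eqn{H} in nm.
#' @param sigma lateral standard deviation \eqn{\sigma} in nm.
#' @return a \linkS4class{HeightField}.
#' @export
genBlob <- function(nrow, ncol, pixelSize, center, height, sigma) {
  if (height <= 0 || sigma <= 0) stopf("height and sigma must be positive")
  x <- (0:(ncol - 1)) * pixelSize
  y <- (0:(nrow - 1)) * pixelSize
  r2 <- outer((y - center[2])^2, (x - center[1])^2, `+`)
  HeightField(height * exp(-r2 / (2 * sigma^2)), pixelSize,
              title = "synthetic blob")
}

#' Generate a worm-like fibril
#'
#' A ridge of Gaussian cross-section (height \code{height}, width
#' \code{widthSigma}) along a discrete worm-like path: the heading performs
#' a random walk with per-step standard deviation \code{directionSd}
#' (radians). With a \code{target}, the heading is additionally steered
#' toward the target point each step (entangled, core-connecting mode);
#' without one the path runs outward from its anchor (radial mode). Paths
#' reflect at the raster border. The defaults (height 3 nm, width sigma
#' 6 nm) are typical surface-bound amyloid fibril dimensions.
#'
#' @param nrow,ncol raster size in pixels.
#' @param pixelSize pixel spacing in nm.
#' @param anchor numeric(2) physical start point \code{c(x, y)} in nm.
#' @param contourLength total path length in nm.
#' @param stepLength path discretization step in nm (default 10).
#' @param directionSd heading change SD per step in radians (default 0.15).
#' @param height ridge height in nm (default 3).
#' @param widthSigma cross-section Gaussian sigma in nm (default 6).
#' @param initialAngle initial heading in radians (random when NULL).
#' @param target optional numeric(2) end point to steer toward.
#' @param targetGain steering weight per step toward the target (default 0.3).
#' @param seed optional RNG seed.
#' @return a \linkS4class{HeightField}.
#' @export
genFibril <- function(nrow, ncol, pixelSize, anchor, contourLength,
                      stepLength = 10, directionSd = 0.15, height = 3,
                      widthSigma = 6, initialAngle = NULL, target = NULL,
                      targetGain = 0.3, seed = NULL) {
  if (contourLength <= 0 || height <= 0 || widthSigma <= 0 || stepLength <= 0)
    stopf("contourLength, stepLength, height and widthSigma must be positive")
  xmax <- (ncol - 1) * pixelSize
  ymax <- (nrow - 1) * pixelSize
  path <- withSeed(seed, {
    ang <- if (is.null(initialAngle)) runif(1, 0, 2 * pi) else initialAngle
    nStep <- max(1L, ceiling(contourLength / stepLength))
    pts <- matrix(NA_real_, nStep + 1L, 2L)
    pts[1, ] <- anchor
    p <- anchor
    for (s in seq_len(nStep)) {
      if (!is.null(target)) {
        bearing <- atan2(target[2] - p[2], target[1] - p[1])
        d <- bearing - ang
        ang <- ang + targetGain * atan2(sin(d), cos(d))
        if (sqrt(sum((target - p)^2)) <= stepLength) {
          pts[s + 1L, ] <- target
          pts <- pts[seq_len(s + 1L), , drop = FALSE]
          break
        }
      }
      ang <- ang + rnorm(1, 0, directionSd)
      q <- p + stepLength * c(cos(ang), sin(ang))
      if (q[1] < 0 || q[1] > xmax) { ang <- pi - ang
        q <- p + stepLength * c(cos(ang), sin(ang)) }
      if (q[2] < 0 || q[2] > ymax) { ang <- -ang
        q <- p + stepLength * c(cos(ang), sin(ang)) }
      pts[s + 1L, ] <- q
      p <- q
    }
    pts[!is.na(pts[, 1]), , drop = FALSE]
  })
  h <- matrix(0, nrow, ncol)
  reach <- 4 * widthSigma
  for (s in seq_len(nrow(path) - 1L)) {
    p <- path[s, ]; q <- path[s + 1L, ]
    j0 <- max(0, floor((min(p[1], q[1]) - reach) / pixelSize))
    j1 <- min(ncol - 1, ceiling((max(p[1], q[1]) + reach) / pixelSize))
    i0 <- max(0, floor((min(p[2], q[2]) - reach) / pixelSize))
    i1 <- min(nrow - 1, ceiling((max(p[2], q[2]) + reach) / pixelSize))
    if (j1 < j0 || i1 < i0) next
    xs <- (j0:j1) * pixelSize
    ys <- (i0:i1) * pixelSize
    v <- q - p
    len2 <- sum(v^2)
    PX <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    PY <- matrix(ys, length(ys), length(xs))
    t <- if (len2 > 0) pmin(pmax(((PX - p[1]) * v[1] + (PY - p[2]) * v[2]) / len2, 0), 1)
         else 0
    d2 <- (PX - (p[1] + t * v[1]))^2 + (PY - (p[2] + t * v[2]))^2
    contrib <- height * exp(-d2 / (2 * widthSigma^2))
    win <- h[(i0 + 1L):(i1 + 1L), (j0 + 1L):(j1 + 1L)]
    h[(i0 + 1L):(i1 + 1L), (j0 + 1L):(j1 + 1L)] <- pmax(win, contrib)
  }
  out <- HeightField(h, pixelSize, title = "synthetic fibril")
  attr(out, "path") <- path
  out
}

#' Compose a synthetic AFM scene with exact ground truth
#'
#' Builds substrate (flat Gaussian roughness, or ripple plus optional
#' long-range roughness), adds planted aggregates (blobs and fibrils,
#' combined by pointwise maximum so that crossing deposits do not stack),
#' and finally applies instrument white noise and per-scan-line offsets.
#' The ground truth (substrate-only field, aggregate-only field, aggregate
#' ownership masks and true zero-basis volumes) is recorded before noise.
#'
#' The RNG is consumed in a fixed order under \code{spec$seed}: surface
#' components first (ripple jitter, then long-range roughness), then
#' aggregates in list order, then instrument noise, then scan-line offsets;
#' a fixed seed therefore reproduces the scene bit for bit.
#'
#' @param spec a SceneSpec list with elements \code{raster} (nrow, ncol,
#'   pixelSize), \code{surface} (\code{type = "flat"} with \code{sigma}, or
#'   \code{type = "rippled"} with \code{wavelength}, \code{amplitudePp},
#'   \code{jitterSd}, \code{axis}, optional \code{longRange} = list(rms,
#'   corrLength)), \code{aggregates} (list of blob/fibril specs, see
#'   \code{\link{genBlob}} and \code{\link{genFibril}}), \code{instrument}
#'   (\code{noiseSd}, \code{rowOffsetSd}) and \code{seed}.
#' @return list with \code{field} (the composed \linkS4class{HeightField})
#'   and \code{truth} (a \linkS4class{SceneGroundTruth}).
#' @export
genScene <- function(spec) {
  ras <- spec$raster
  nr <- ras$nrow; nc <- ras$ncol; px <- ras$pixelSize
  if (is.null(nr) || is.null(nc) || is.null(px) || px <= 0)
    stopf("spec$raster must give nrow, ncol and a positive pixelSize")
  surf <- spec$surface
  inst <- spec$instrument %||% list(noiseSd = 0, rowOffsetSd = 0)
  aggs <- spec$aggregates %||% list()
  maskEps <- 0.01   # nm; aggregate ownership cutoff
  withSeed(spec$seed, {
    surfParams <- list(type = surf$type)
    substrate <- if (identical(surf$type, "flat")) {
      surfParams$sigma <- surf$sigma
      matrix(rnorm(nr * nc, 0, surf$sigma), nr, nc)
    } else if (identical(surf$type, "rippled")) {
      rip <- genRipple(nr, nc, px, surf$wavelength, surf$amplitudePp,
                       surf$jitterSd %||% 0, surf$axis %||% "x")
      surfParams$wavelength <- surf$wavelength
      surfParams$amplitudePp <- surf$amplitudePp
      s <- heights(rip)
      if (!is.null(surf$longRange)) {
        lr <- genLongRangeRoughness(nr, nc, px, surf$longRange$rms,
                                    surf$longRange$corrLength)
        surfParams$longRange <- surf$longRange
        s <- s + heights(lr)
      }
      s
    } else stopf("unknown surface type: %s", surf$type)
    aggFields <- lapply(aggs, function(a) {
      if (identical(a$kind, "blob"))
        heights(genBlob(nr, nc, px, c(a$x, a$y), a$height, a$sigma))
      else if (identical(a$kind, "fibril"))
        heights(genFibril(nr, nc, px, c(a$x, a$y), a$length,
                          a$stepLength %||% 10, a$directionSd %||% 0.15,
                          a$height %||% 3, a$widthSigma %||% 6,
                          initialAngle = a$angle,
                          target = if (!is.null(a$targetX)) c(a$targetX, a$targetY)))
      else stopf("unknown aggregate kind: %s", a$kind)
    })
    aggComposite <- matrix(0, nr, nc)
    masks <- matrix(0L, nr, nc)
    best <- matrix(0, nr, nc)
    for (k in seq_along(aggFields)) {
      f <- aggFields[[k]]
      sel <- f > best & f > maskEps
      masks[sel] <- k
      best <- pmax(best, f)
      aggComposite <- pmax(aggComposite, f)
    }
    trueVolumes <- if (length(aggFields) > 0)
      vapply(seq_along(aggFields), function(k)
        sum(aggComposite[masks == k]) * px * px, numeric(1))
    else numeric(0)
    composed <- substrate + aggComposite
    if ((inst$noiseSd %||% 0) > 0)
      composed <- composed + matrix(rnorm(nr * nc, 0, inst$noiseSd), nr, nc)
    if ((inst$rowOffsetSd %||% 0) > 0)
      composed <- composed + rnorm(nr, 0, inst$rowOffsetSd)
    truth <- new("SceneGroundTruth",
                 substrateField = HeightField(substrate, px, title = "substrate"),
                 aggregateField = HeightField(aggComposite + 0, px,
                                              title = "aggregates"),
                 masks = masks, trueVolumes = trueVolumes,
                 surfaceParams = surfParams, spec = spec)
    list(field = HeightField(composed, px, title = spec$title %||% "scene"),
         truth = truth)
  })
}

#' Ground-truth zero-basis volumes above a threshold
#'
#' For each planted aggregate: the integral of the aggregate-only field over
#' the pixels of its mask exceeding the threshold -- the quantity the
#' segmentation pipeline should recover from the composed, filtered image.
#'
#' @param truth a \linkS4class{SceneGroundTruth}.
#' @param threshold height threshold in nm (0 for the full planted volume).
#' @return numeric vector of volumes (nm^3), one per planted aggregate.
#' @export
trueVolumesAbove <- function(truth, threshold = 0) {
  stopifnot(is(truth, "SceneGroundTruth"))
  agg <- heights(truth@aggregateField)
  px <- pixelSize(truth@aggregateField)
  vapply(seq_along(truth@trueVolumes), function(k) {
    sel <- truth@masks == k & agg > threshold
    sum(agg[sel]) * px[1] * px[2]
  }, numeric(1))
}

# analytic volume helpers used when matching scene presets
blobPlantedVolume <- function(height, sigma) 2 * pi * sigma^2 * height
fibrilPlantedVolume <- function(length, height = 3, widthSigma = 6)
  length * height * sqrt(2 * pi) * widthSigma

#' Built-in scene presets
#'
#' Declarative SceneSpec presets for the study conditions the generator
#' emulates:
#' \describe{
#'   \item{flat}{untreated-wafer substrate: uncorrelated roughness,
#'     Sq 0.2 nm, no aggregates.}
#'   \item{nanopatterned}{ion-irradiated substrate: ripple of wavelength
#'     29.3 nm and peak-to-peak amplitude 1.5 nm plus long-range roughness
#'     (rms 1.08 nm, correlation length 300 nm), no aggregates.}
#'   \item{filterTest}{ripple substrate (no long-range component) with
#'     three amorphous blobs and two fibrils at seeded random positions --
#'     the recovery scene for notch-filter fidelity.}
#'   \item{radial}{flat substrate with one amorphous core and eight
#'     low-curvature fibrils growing radially outward -- the frayed,
#'     star-like morphology.}
#'   \item{entangled}{flat substrate with two amorphous cores connected by
#'     high-curvature fibrils, core heights chosen so the total planted
#'     volume matches the radial preset -- the compact morphology.}
#' }
#' All presets use a 512 x 512 raster over (1 um)^2.
#'
#' @param name preset name.
#' @param seed RNG seed stored in the spec (also drives seeded positions in
#'   \code{filterTest}).
#' @return a SceneSpec list for \code{\link{genScene}}.
#' @export
scenePreset <- function(name = c("flat", "nanopatterned", "filterTest",
                                 "radial", "entangled"), seed = 1L) {
  name <- match.arg(name)
  ras <- list(nrow = 512L, ncol = 512L, pixelSize = 1000 / 512)
  base <- list(raster = ras, seed = seed, title = name,
               instrument = list(noiseSd = 0.05, rowOffsetSd = 0.2))
  rippled <- list(type = "rippled", wavelength = 29.3, amplitudePp = 1.5,
                  jitterSd = 0, axis = "x")
  if (name == "flat") {
    base$surface <- list(type = "flat", sigma = 0.2)
  } else if (name == "nanopatterned") {
    base$surface <- c(rippled,
                      list(longRange = list(rms = 1.08, corrLength = 300)))
  } else if (name == "filterTest") {
    base$surface <- rippled
    base$aggregates <- withSeed(seed + 1000L, {
      pos <- matrix(NA_real_, 0, 2)
      while (nrow(pos) < 3L) {
        p <- runif(2, 220, 780)
        if (nrow(pos) == 0L || min(sqrt(colSums((t(pos) - p)^2))) > 260)
          pos <- rbind(pos, p)
      }
      hgt <- runif(3, 25, 120)
      sig <- runif(3, 25, 45)
      blobs <- lapply(1:3, function(k)
        list(kind = "blob", x = pos[k, 1], y = pos[k, 2],
             height = hgt[k], sigma = sig[k]))
      fibs <- lapply(1:2, function(k)
        list(kind = "fibril", x = runif(1, 150, 850), y = runif(1, 150, 850),
             length = runif(1, 800, 1200), angle = runif(1, 0, 2 * pi),
             directionSd = 0.1))
      c(blobs, fibs)
    })
  } else if (name == "radial") {
    base$surface <- list(type = "flat", sigma = 0.2)
    core <- list(kind = "blob", x = 500, y = 500, height = 25, sigma = 30)
    fibs <- lapply(0:7, function(k)
      list(kind = "fibril", x = 500, y = 500, length = 700,
           angle = 2 * pi * k / 8, directionSd = 0.03))
    base$aggregates <- c(list(core), fibs)
  } else if (name == "entangled") {
    base$surface <- list(type = "flat", sigma = 0.2)
    # match the radial preset's total planted volume with two fatter cores
    totalRadial <- blobPlantedVolume(25, 30) + 8 * fibrilPlantedVolume(700)
    fibLen <- 430   # typical steered path length between the cores
    coreH <- (totalRadial - 3 * fibrilPlantedVolume(fibLen)) /
      (2 * 2 * pi * 40^2)
    cores <- list(
      list(kind = "blob", x = 320, y = 500, height = coreH, sigma = 40),
      list(kind = "blob", x = 680, y = 500, height = coreH, sigma = 40))
    fibs <- lapply(1:3, function(k)
      list(kind = "fibril", x = 320, y = 500, length = 900,
           targetX = 680, targetY = 500, directionSd = 0.25))
    base$aggregates <- c(cores, fibs)
  }
  base
}
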