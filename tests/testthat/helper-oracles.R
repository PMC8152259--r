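# Independent oracles used across the suite.

# Brute-force mid-edge marching-squares tracer: walks every 2x2 window of
# the zero-padded mask and sums hand-enumerated segment endpoint distances.
# Deliberately written from the contour geometry (explicit coordinates),
# not from a length lookup table.
bruteBoundary <- function(mask, ps = c(1, 1)) {
  nr <- nrow(mask); nc <- ncol(mask)
  P <- matrix(FALSE, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- mask
  px <- ps[1]; py <- ps[2]
  segsFor <- function(a, b, cc, d) {
    # corners: a = TL (0,0), b = TR (px,0), cc = BL (0,py), d = BR (px,py)
    top <- c(px / 2, 0); bot <- c(px / 2, py)
    lef <- c(0, py / 2); rig <- c(px, py / 2)
    fg <- c(a, b, cc, d)
    segs <- list()
    addseg <- function(p, q) segs[[length(segs) + 1L]] <<- rbind(p, q)
    n <- sum(fg)
    if (n == 1L || n == 3L) {
      corner <- if (n == 1L) which(fg) else which(!fg)
      if (corner == 1L) addseg(top, lef)
      if (corner == 2L) addseg(top, rig)
      if (corner == 3L) addseg(bot, lef)
      if (corner == 4L) addseg(bot, rig)
    } else if (n == 2L) {
      if (a && b) addseg(lef, rig)
      else if (cc && d) addseg(lef, rig)
      else if (a && cc) addseg(top, bot)
      else if (b && d) addseg(top, bot)
      else if (a && d) { addseg(top, rig); addseg(bot, lef) }
      else if (b && cc) { addseg(top, lef); addseg(bot, rig) }
    }
    segs
  }
  total <- 0
  for (i in seq_len(nr + 1L)) for (j in seq_len(nc + 1L)) {
    segs <- segsFor(P[i, j], P[i, j + 1L], P[i + 1L, j], P[i + 1L, j + 1L])
    for (s in segs) total <- total + sqrt(sum((s[1, ] - s[2, ])^2))
  }
  total
}

# Closed-form zero-basis volume of a Gaussian blob above a threshold:
# integral of H exp(-r^2 / 2 sigma^2) over { h > t } = 2 pi sigma^2 (H - t)
blobVolumeAbove <- function(H, sigma, t) 2 * pi * sigma^2 * (H - t)

# Match measured grains to planted blob centres; returns relative volume
# errors in blob order.
matchGrainVolumes <- function(morph, scene, threshold) {
  tv <- trueVolumesAbove(scene$truth, threshold)
  blobs <- Filter(function(a) a$kind == "blob", scene$truth@spec$aggregates)
  bx <- vapply(blobs, `[[`, numeric(1), "x")
  by <- vapply(blobs, `[[`, numeric(1), "y")
  vapply(seq_len(nrow(morph)), function(g) {
    k <- which.min((bx - morph$centroidXNm[g])^2 + (by - morph$centroidYNm[g])^2)
    morph$volumeNm3[g] / tv[k] - 1
  }, numeric(1))
}

# White-noise height field
noiseField <- function(n, sigma, pixelSize = 1000 / n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  HeightField(matrix(rnorm(n * n, 0, sigma), n, n), pixelSize)
}
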