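pxStd <- 1000 / 512

test_that("ripple generator is deterministic, Nyquist-guarded, exact in Sq", {
  r1 <- genRipple(128, 128, pxStd, 29.3, 1.5, jitterSd = 2, seed = 5)
  r2 <- genRipple(128, 128, pxStd, 29.3, 1.5, jitterSd = 2, seed = 5)
  expect_identical(heights(r1), heights(r2))
  expect_error(genRipple(64, 64, 10, 15, 1.5), "Nyquist")
  rip <- genRipple(256, 512, pxStd, 31.25, 1.5)   # integer periods
  expect_lt(abs(sq(rmsRoughness(rip)) / (1.5 / (2 * sqrt(2))) - 1), 0.01)
  expect_lt(abs(mean(heights(rip))), 1e-12)
})

test_that("jitter-free and jittered ripples are recovered by the HDCF", {
  m0 <- rippleMetricsFromHdcf(hdcf1D(genRipple(128, 512, pxStd, 29.3, 1.5), "x"))
  expect_lt(abs(m0@periodicity - 29.3) / 29.3, 0.02)
  mj <- rippleMetricsFromHdcf(hdcf1D(
    genRipple(512, 512, pxStd, 29.3, 1.5, jitterSd = 2, seed = 6), "x"))
  expect_true(mj@detected)
  expect_lt(abs(mj@periodicity - 29.3) / 29.3, 0.1)
})

test_that("long-range roughness has the designed correlation structure", {
  z <- genLongRangeRoughness(256, 256, pxStd, 0, 300)
  expect_true(all(heights(z) == 0))
  # constrained synthesis: every sample attains the target rms exactly
  sqs <- vapply(1:5, function(s)
    sq(rmsRoughness(genLongRangeRoughness(256, 256, 1000 / 256, 1.0, 100,
                                          seed = s))), numeric(1))
  expect_equal(sqs, rep(1, 5), tolerance = 1e-9)
  # distinct seeds give distinct fields
  f1 <- genLongRangeRoughness(128, 128, 4, 1, 50, seed = 1)
  f2 <- genLongRangeRoughness(128, 128, 4, 1, 50, seed = 2)
  expect_gt(mean(abs(heights(f1) - heights(f2))), 0.1)
  # autocorrelation at one correlation length is about exp(-1/2)
  px256 <- 1000 / 256
  d <- round(60 / px256)
  expectedAc <- exp(-(d * px256)^2 / (2 * 60^2))
  acors <- vapply(1:8, function(s) {
    f <- genLongRangeRoughness(256, 256, px256, 1.0, 60, seed = 100 + s)
    h <- heights(f)
    c1 <- mean(h[, 1:(256 - d)] * h[, (1 + d):256])
    c1 / mean(h^2)
  }, numeric(1))
  expect_lt(abs(mean(acors) - expectedAc), 0.08)
  expect_error(genLongRangeRoughness(64, 64, 4, 1, 2), "exceed")
})

test_that("blob fields integrate to their closed-form volumes", {
  blob <- genBlob(512, 512, pxStd, c(500, 500), 50, 30)
  full <- sum(heights(blob)) * pxStd^2
  expect_lt(abs(full / (2 * pi * 30^2 * 50) - 1), 0.01)
  lm <- markByThreshold(blob, 10)
  expect_lt(abs(zeroBasisVolume(blob, lm, 1) /
                blobVolumeAbove(50, 30, 10) - 1), 0.03)
  expect_error(genBlob(64, 64, 2, c(10, 10), -1, 5), "positive")
})

test_that("fibril footprint matches its length times the level-set width", {
  fib <- genFibril(512, 512, pxStd, c(200, 500), 1000, stepLength = 10,
                   directionSd = 0.05, height = 3, widthSigma = 6, seed = 9,
                   initialAngle = 0.3)
  t <- 1.5
  area <- sum(heights(fib) > t) * pxStd^2
  wEff <- 2 * 6 * sqrt(2 * log(3 / t))   # Gaussian ridge level-set width
  expect_lt(abs(area / (1000 * wEff) - 1), 0.15)
  expect_error(genFibril(64, 64, 2, c(10, 10), -5), "positive")
})

test_that("radial fibrils touch their core; entangled fibrils join two cores", {
  scR <- genScene(scenePreset("radial", seed = 3))
  masks <- scR$truth@masks
  core <- masks == 1L
  coreGrown <- EBImage::dilate(matrix(as.numeric(core), nrow(core)),
                               EBImage::makeBrush(5, "box")) > 0
  for (k in 2:9) expect_true(any(coreGrown & masks == k))
  scE <- genScene(scenePreset("entangled", seed = 3))
  agg <- heights(scE$truth@aggregateField)
  spec <- scE$truth@spec
  cores <- Filter(function(a) a$kind == "blob", spec$aggregates)
  for (k in 3:5) {   # fibrils are aggregates 3..5
    fib <- scE$truth@masks == k
    w <- which(fib, arr.ind = TRUE)
    xy <- cbind((w[, 2] - 1) * pxStd, (w[, 1] - 1) * pxStd)
    d1 <- min(sqrt((xy[, 1] - cores[[1]]$x)^2 + (xy[, 2] - cores[[1]]$y)^2))
    d2 <- min(sqrt((xy[, 1] - cores[[2]]$x)^2 + (xy[, 2] - cores[[2]]$y)^2))
    expect_lt(d1, 80); expect_lt(d2, 80)
  }
})

test_that("scenes compose reproducibly with exact ground truth", {
  spec <- scenePreset("filterTest", seed = 12)
  s1 <- genScene(spec); s2 <- genScene(spec)
  expect_identical(heights(s1$field), heights(s2$field))
  expect_identical(s1$truth@trueVolumes, s2$truth@trueVolumes)
  # composition: substrate + aggregates (pre-noise scene)
  spec$instrument <- list(noiseSd = 0, rowOffsetSd = 0)
  s3 <- genScene(spec)
  recomposed <- heights(s3$truth@substrateField) +
    heights(s3$truth@aggregateField)
  expect_equal(heights(s3$field), recomposed)
  # a flat scene with no aggregates yields no grains at the study threshold
  flat <- genScene(scenePreset("flat", seed = 1))
  expect_equal(max(labels2D(markByThreshold(flat$field, 8.2))), 0L)
})

test_that("overlapping aggregates combine by pointwise maximum", {
  spec <- list(raster = list(nrow = 64, ncol = 64, pixelSize = 4),
               surface = list(type = "flat", sigma = 0),
               aggregates = list(
                 list(kind = "blob", x = 120, y = 128, height = 20, sigma = 30),
                 list(kind = "blob", x = 140, y = 128, height = 10, sigma = 30)),
               instrument = list(noiseSd = 0, rowOffsetSd = 0), seed = 1)
  s <- genScene(spec)
  b1 <- heights(genBlob(64, 64, 4, c(120, 128), 20, 30))
  b2 <- heights(genBlob(64, 64, 4, c(140, 128), 10, 30))
  expect_equal(heights(s$field), pmax(b1, b2))
})

test_that("component variances add in quadrature for composed substrates", {
  rels <- vapply(1:8, function(s) {
    rip <- genRipple(256, 256, 1000 / 256, 29.3, 1.5, jitterSd = 0)
    lr <- genLongRangeRoughness(256, 256, 1000 / 256, 1.08, 300, seed = 400 + s)
    vc <- mean((heights(rip) + heights(lr) -
                mean(heights(rip) + heights(lr)))^2)
    vr <- mean((heights(rip) - mean(heights(rip)))^2)
    vl <- mean((heights(lr) - mean(heights(lr)))^2)
    vc / (vr + vl) - 1
  }, numeric(1))
  expect_lt(abs(mean(rels)), 0.1)
})

test_that("the full pipeline recovers planted blob volumes and counts", {
  errs <- c()
  for (s in 1:5) {
    scene <- genScene(scenePreset("filterTest", seed = 500 + s))
    res <- analyzeField(scene$field, threshold = 8.2)
    m <- res$morphometrics
    expect_equal(nrow(m), 3L)   # three planted blobs; fibrils sit below 8.2 nm
    errs <- c(errs, abs(matchGrainVolumes(m, scene, 8.2)))
  }
  expect_lt(median(errs), 0.05)
})
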