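test_that("threshold segmentation counts and orders grains correctly", {
  px <- 1000 / 512
  b1 <- genBlob(512, 512, px, c(250, 500), 30, 30)
  b2 <- genBlob(512, 512, px, c(750, 500), 30, 30)
  f <- HeightField(heights(b1) + heights(b2), px)
  lm <- markByThreshold(f, 8.2)
  expect_equal(max(labels2D(lm)), 2L)
  # labels in raster-scan order of the topmost-leftmost pixel:
  # both blobs peak on the same row band; leftmost (x = 250) is grain 1
  gs <- grainSummary(f, lm)
  expect_lt(gs$centroidXNm[1], gs$centroidXNm[2])
  expect_equal(max(labels2D(markByThreshold(f, 40))), 0L)
  lmTop <- markByThreshold(f, 0.99 * max(heights(f)))
  expect_gte(max(labels2D(lmTop)), 1L)
  expect_lt(sum(labels2D(lmTop) > 0), 30)
  expect_error(markByThreshold(f, -1), "positive")
})

test_that("8-connectivity joins diagonals, 4-connectivity splits them", {
  h <- matrix(0, 8, 8)
  h[3, 3] <- 10; h[4, 4] <- 10; h[5, 5] <- 10
  f <- HeightField(h, 1)
  expect_equal(max(labels2D(markByThreshold(f, 5, connectivity = 8))), 1L)
  expect_equal(max(labels2D(markByThreshold(f, 5, connectivity = 4))), 3L)
})

test_that("small components are discarded by minAreaPx", {
  h <- matrix(0, 16, 16)
  h[2, 2] <- 10            # 1 px speck
  h[8:11, 8:11] <- 10      # 16 px grain
  f <- HeightField(h, 1)
  lm <- markByThreshold(f, 5, minAreaPx = 4)
  expect_equal(max(labels2D(lm)), 1L)
  expect_equal(sum(labels2D(lm) > 0), 16L)
})

test_that("zero-basis volume is the height integral from z = 0", {
  h <- matrix(0, 8, 8); h[4, 4] <- 10
  f <- HeightField(h, 2)
  lm <- markByThreshold(f, 5)
  expect_equal(zeroBasisVolume(f, lm, 1), 10 * 2 * 2)
  expect_error(zeroBasisVolume(f, lm, 7), "no grain")
  h2 <- matrix(0, 16, 16); h2[4:13, 4:13] <- 10
  f2 <- HeightField(h2, 2)
  expect_equal(zeroBasisVolume(f2, markByThreshold(f2, 5), 1), 100 * 10 * 4)
})

test_that("Gaussian blob volume matches the closed-form integral", {
  px <- 1000 / 512
  blob <- genBlob(512, 512, px, c(500, 500), 50, 30)
  lm <- markByThreshold(blob, 8.2)
  v <- zeroBasisVolume(blob, lm, 1)
  expect_lt(abs(v / blobVolumeAbove(50, 30, 8.2) - 1), 0.03)
})

test_that("mid-edge boundary length matches hand-derived constants", {
  for (p in c(1, 2.5)) {
    h <- matrix(0, 9, 9); h[5, 5] <- 10
    lm1 <- markByThreshold(HeightField(h, p), 5)
    expect_equal(boundaryLength(lm1, 1), 2 * sqrt(2) * p)
    h2 <- matrix(0, 9, 9); h2[4:5, 4:5] <- 10
    lm2 <- markByThreshold(HeightField(h2, p), 5)
    expect_equal(boundaryLength(lm2, 1), 4 * p + 2 * sqrt(2) * p)
  }
  expect_error(boundaryLength(markByThreshold(HeightField(matrix(c(0, 9, 0, 0), 2, 2), 1), 5), 3),
               "no grain")
})

test_that("mid-edge boundary agrees with the brute-force tracer on every 2x2 configuration", {
  for (code in 1:15) {
    m <- matrix(FALSE, 4, 4)
    m[2, 2] <- bitwAnd(code, 1L) > 0
    m[2, 3] <- bitwAnd(code, 2L) > 0
    m[3, 2] <- bitwAnd(code, 4L) > 0
    m[3, 3] <- bitwAnd(code, 8L) > 0
    got <- afmorph:::maskBoundaryLength(m, c(1, 1))
    expect_equal(got, bruteBoundary(m), info = paste("config", code))
  }
})

test_that("interpolated boundary of a large sloped disk converges to 2 pi R", {
  n <- 301; Rpx <- 100
  xy <- (1:n) - 151
  r <- sqrt(outer(xy^2, xy^2, `+`))
  cone <- pmax(10 * (1 - r / (2 * Rpx)), 0)   # h > 5 exactly inside r < 100
  f <- HeightField(cone, 1)
  lm <- markByThreshold(f, 5)
  expect_lt(abs(boundaryLength(lm, 1, f) / (2 * pi * Rpx) - 1), 0.03)
})

test_that("volume and boundary are invariant under transposition", {
  px <- 1
  set.seed(17)
  h <- matrix(0, 64, 64)
  h[20:40, 15:45] <- 10 + matrix(rnorm(21 * 31), 21, 31)
  f <- HeightField(h, px); ft <- HeightField(t(h), px)
  lm <- markByThreshold(f, 5); lmt <- markByThreshold(ft, 5)
  expect_equal(zeroBasisVolume(f, lm, 1), zeroBasisVolume(ft, lmt, 1))
  expect_equal(boundaryLength(lm, 1, f), boundaryLength(lmt, 1, ft))
})

test_that("boundary respects the isoperimetric lower bound", {
  # no planar region beats the disk: L >= 2 sqrt(pi A), with 5 percent
  # slack for discretization
  px <- 1000 / 512
  for (s in 1:5) {
    blob <- genBlob(256, 256, px, c(250 + 20 * s, 250), 20 + 5 * s, 15 + 3 * s)
    lm <- markByThreshold(blob, 8.2)
    gs <- grainSummary(blob, lm)
    expect_gt(gs$boundaryNm * 1.05, 2 * sqrt(pi * gs$areaNm2))
  }
})

test_that("spreading coefficient is the exact ratio and scales as 1/s", {
  expect_equal(spreadingCoefficient(5, 10), 2)
  expect_error(spreadingCoefficient(0, 10), "positive")
  # lateral magnification by s: L x s, V x s^2, spreading x 1/s
  h <- matrix(0, 32, 32); h[10:20, 10:20] <- 12
  f1 <- HeightField(h, 1); f2 <- HeightField(h, 3)
  lm1 <- markByThreshold(f1, 5); lm2 <- markByThreshold(f2, 5)
  v1 <- zeroBasisVolume(f1, lm1, 1); v2 <- zeroBasisVolume(f2, lm2, 1)
  b1 <- boundaryLength(lm1, 1, f1); b2 <- boundaryLength(lm2, 1, f2)
  expect_equal(v2, v1 * 9)
  expect_equal(b2, b1 * 3)
  expect_equal(spreadingCoefficient(v2, b2), spreadingCoefficient(v1, b1) / 3)
  # height-only doubling halves the spreading
  fH <- HeightField(2 * h, 1)
  lmH <- markByThreshold(fH, 5)
  vH <- zeroBasisVolume(fH, lmH, 1)
  expect_equal(spreadingCoefficient(vH, boundaryLength(lmH, 1)),
               spreadingCoefficient(v1, boundaryLength(lm1, 1)) / 2)
})

test_that("every labelled pixel exceeds the threshold and areas fit the raster", {
  px <- 1000 / 512
  scene <- genScene(scenePreset("filterTest", seed = 7))
  f <- scene$field
  lm <- markByThreshold(f, 8.2)
  L <- labels2D(lm)
  expect_true(all(heights(f)[L > 0] > 8.2))
  gs <- grainSummary(f, lm)
  expect_lte(sum(gs$areaNm2), 512 * 512 * px * px)
})

test_that("artefact rules filter deterministically with provenance", {
  m <- data.frame(grainId = 1:4, areaNm2 = c(100, 5000, 3000, 800),
                  volumeNm3 = c(10, 500, 300, 80),
                  boundaryNm = c(5, 50, 40, 20),
                  spreadingPerNm2 = c(0.5, 0.1, 0.13, 0.25),
                  maxHeightNm = c(1.2, 40, 25, 9),
                  centroidXNm = c(10, 500, 900, 100),
                  centroidYNm = c(10, 500, 900, 100),
                  borderFlag = FALSE)
  out <- excludeArtefacts(m, list(minArea = 1000))
  expect_equal(out$keptFlag, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$rule[1], "min_area")
  out2 <- excludeArtefacts(m, list(
    excludeRegions = data.frame(xmin = 800, xmax = 1000, ymin = 800, ymax = 1000)))
  expect_equal(out2$keptFlag, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(out2$rule[3], "exclude_region")
  out3 <- excludeArtefacts(m, list())
  expect_true(all(out3$keptFlag))
  out4 <- excludeArtefacts(m, list(minArea = 1000, keep = 1L))
  expect_true(out4$keptFlag[1])
  expect_error(excludeArtefacts(m, list(keep = 2L, drop = 2L)), "both keep and drop")
})

test_that("the auto threshold tracks the background, not the aggregates", {
  set.seed(23)
  bg <- matrix(rnorm(256^2, 0, 0.2), 256)
  f0 <- HeightField(bg, 2)
  thr0 <- autoThreshold(f0)
  expect_lt(abs(thr0 - 5 * 0.2), 0.15)
  withBlob <- bg
  withBlob[100:150, 100:150] <- withBlob[100:150, 100:150] + 60
  thr1 <- autoThreshold(HeightField(withBlob, 2))
  expect_lt(abs(thr1 - thr0), 0.3)
})
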