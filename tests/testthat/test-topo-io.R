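test_that("GSF write/read round-trips and is byte-stable", {
  set.seed(4)
  h <- matrix(round(rnorm(64 * 48, 5, 2), 3), 48, 64)
  # push values through float32 once so the round trip is exact
  tmp1 <- tempfile(fileext = ".gsf")
  writeGSF(HeightField(h, c(1.5, 2.0), title = "test field"), tmp1)
  f1 <- readGSF(tmp1)
  expect_equal(pixelSize(f1), c(1.5, 2.0))
  expect_equal(heights(f1), h, tolerance = 1e-6)
  expect_equal(f1@title, "test field")
  tmp2 <- tempfile(fileext = ".gsf")
  writeGSF(f1, tmp2)
  expect_identical(readBin(tmp1, "raw", file.size(tmp1)),
                   readBin(tmp2, "raw", file.size(tmp2)))
  f2 <- readGSF(tmp2)
  expect_identical(heights(f2), heights(f1))
})

test_that("a hand-written GSF parses with the documented layout", {
  hdr <- "Gwyddion Simple Field 1.0\nXRes = 2\nYRes = 2\nXReal = 2\nYReal = 2\n"
  tmp <- tempfile(fileext = ".gsf")
  con <- file(tmp, "wb")
  writeBin(charToRaw(hdr), con)
  writeBin(raw(4 - nchar(hdr) %% 4), con)
  writeBin(c(0, 1, 2, 3), con, size = 4, endian = "little")
  close(con)
  f <- readGSF(tmp)
  expect_equal(heights(f), matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE))
  expect_equal(pixelSize(f), c(1, 1))
})

test_that("GSF errors: bad magic, payload mismatch, non-finite heights", {
  tmp <- tempfile(fileext = ".gsf")
  writeLines("Not a GSF file", tmp)
  writeBin(c(readBin(tmp, "raw", file.size(tmp)), as.raw(0)), tmp)
  expect_error(readGSF(tmp), "magic")

  hdr <- "Gwyddion Simple Field 1.0\nXRes = 4\nYRes = 4\nXReal = 4\nYReal = 4\n"
  con <- file(tmp, "wb")
  writeBin(charToRaw(hdr), con)
  writeBin(raw(4 - nchar(hdr) %% 4), con)
  writeBin(c(0, 1, 2), con, size = 4, endian = "little")  # 3 of 16 values
  close(con)
  expect_error(readGSF(tmp), "payload size")

  bad <- matrix(1, 4, 4); bad[2, 2] <- NaN
  f <- new("HeightField", heights = matrix(1, 4, 4), pixelSize = c(1, 1),
           title = "", zUnits = "nm")
  f@heights <- bad
  out <- tempfile(fileext = ".gsf")
  expect_error(writeGSF(f, out), "finite")
  expect_false(file.exists(out))
})

test_that("ASCII grid round-trips, skips comments, rejects bad input", {
  tmp <- tempfile(fileext = ".txt")
  writeLines(c("# a comment", "0 1", "2 3"), tmp)
  f <- readASCIIGrid(tmp, pixelSize = 1)
  expect_equal(heights(f), matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE))

  set.seed(9)
  g <- HeightField(matrix(rnorm(64 * 64), 64), 2.5)
  writeASCIIGrid(g, tmp)
  expect_lt(max(abs(heights(readASCIIGrid(tmp, 2.5)) - heights(g))), 1e-9)

  writeLines(c("0 1", "2 3 4"), tmp)
  expect_error(readASCIIGrid(tmp, 1), "ragged")
  writeLines(c("0 1", "2 x"), tmp)
  expect_error(readASCIIGrid(tmp, 1), "non-numeric")
})

test_that("plane levelling removes an exact plane and is idempotent", {
  n <- 64
  X <- matrix((0:(n - 1)), n, n, byrow = TRUE)
  Y <- matrix((0:(n - 1)), n, n)
  f <- HeightField(0.01 * X + 0.02 * Y + 3, 1)
  out <- planeLevel(f)
  expect_lt(max(abs(heights(out))), 1e-9)
  # a centred cosine with integer periods is exactly orthogonal to the
  # plane basis (even about the raster centre), so levelling only removes
  # the mean; a sine phase projects onto the ramp with the small analytic
  # slope -6A/(pi n L), which the fit must reproduce
  cosF <- HeightField(matrix(cos(2 * pi * ((0:(n - 1)) + 0.5) * 4 / n),
                             n, n, byrow = TRUE), 1)
  lev <- planeLevel(cosF)
  expect_lt(max(abs(heights(lev) - (heights(cosF) - mean(heights(cosF))))), 1e-9)
  sinF <- HeightField(matrix(sin(2 * pi * (0:(n - 1)) * 4 / n), n, n,
                             byrow = TRUE), 1)
  levS <- planeLevel(sinF)
  maxChange <- max(abs(heights(levS) - (heights(sinF) - mean(heights(sinF)))))
  slopeBound <- 6 / (pi * 4 * n) * (n / 2)   # |slope| x half-range, A = 1
  expect_lt(maxChange, 1.1 * slopeBound)
  expect_gt(maxChange, 0.5 * slopeBound)
  # idempotence
  twice <- planeLevel(lev)
  expect_lt(max(abs(heights(twice) - heights(lev))), 1e-9)
})

test_that("masked plane levelling ignores protrusions", {
  n <- 64
  X <- matrix((0:(n - 1)), n, n, byrow = TRUE)
  h <- 0.05 * X
  h[20:30, 20:30] <- h[20:30, 20:30] + 50   # a tall deposit
  f <- HeightField(h, 1)
  mask <- h < 10
  out <- planeLevel(f, mask = mask)
  expect_lt(max(abs(heights(out)[mask])), 1e-9)
  expect_gt(min(heights(out)[!mask]), 49)
})

test_that("median line levelling removes scan-line offsets", {
  f <- HeightField(matrix(c(0, 0, 7, 7, -3, -3), 3, 2, byrow = TRUE), 1)
  out <- heights(lineLevelMedian(f))
  expect_lt(max(out) - min(out), 1e-12)
  # offset-free field (identical scan lines) unchanged up to a constant
  g <- genRipple(32, 32, 1, 8, 2)
  lev <- lineLevelMedian(g)
  d <- heights(lev) - heights(g)
  expect_lt(max(d) - min(d), 1e-12)
  # ripple plus per-row offsets: clean ripple recovered
  rip <- genRipple(128, 128, 4, 29.3, 1.5)
  set.seed(3)
  noisy <- HeightField(heights(rip) + rnorm(128, 0, 0.5), 4)
  rec <- lineLevelMedian(noisy)
  resid <- heights(rec) - heights(rip)
  resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)), 0.05)
  # idempotence
  again <- lineLevelMedian(rec)
  expect_lt(max(abs(heights(again) - heights(rec))), 1e-9)
})

test_that("profiles interpolate bilinearly and respect bounds", {
  h <- matrix(rep(1:8, times = 8), 8, 8)  # each row constant at its index
  f <- HeightField(h, 2)
  p <- extractProfile(f, c(0, 4), c(14, 4), nSamples = 8)
  expect_equal(p@heights, rep(3, 8))  # row at y = 4 nm is row 3 (value 3)
  expect_equal(p@positions[1], 0)
  expect_equal(p@positions[8], 14)
  # exact stored values at integer coordinates along a row
  set.seed(11)
  g <- HeightField(matrix(rnorm(64), 8, 8), 1)
  pr <- extractProfile(g, c(0, 3), c(7, 3), nSamples = 8)
  expect_equal(pr@heights, heights(g)[4, ])
  expect_error(extractProfile(f, c(0, 0), c(0, 0), 10), "coincide")
  expect_error(extractProfile(f, c(-1, 0), c(5, 5), 10), "outside")
})

test_that("a profile across a ripple recovers the generating wavelength", {
  rip <- genRipple(256, 256, 1000 / 256, 40, 2)
  p <- extractProfile(rip, c(0, 500), c(990, 500), nSamples = 512)
  # count zero upcrossings to estimate the period
  s <- sign(p@heights)
  ups <- which(diff(s) > 0)
  period <- mean(diff(p@positions[ups]))
  expect_lt(abs(period - 40), p@positions[2] - p@positions[1] + 40 * 0.02)
})

test_that("profile CSV export has the documented columns", {
  rip <- genRipple(64, 64, 4, 40, 2)
  p <- extractProfile(rip, c(0, 100), c(200, 100), nSamples = 32)
  tmp <- tempfile(fileext = ".csv")
  writeProfileCSV(p, tmp)
  d <- read.csv(tmp)
  expect_named(d, c("position_nm", "height_nm"))
  expect_equal(nrow(d), 32)
})
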