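test_that("bilateral filter is the identity on constant images", {
  m <- matrix(0.4, 40, 40)
  out <- denoiseBilateral(m, 3, 0.1)
  expect_equal(out, m, tolerance = 1e-12)
})

test_that("bilateral filter rejects non-positive bandwidths", {
  m <- matrix(0.4, 40, 40)
  expect_error(denoiseBilateral(m, 0, 0.1), "positive")
  expect_error(denoiseBilateral(m, 3, -1), "positive")
})

test_that("bilateral filter matches a brute-force kernel evaluation", {
  set.seed(8)
  m <- matrix(runif(32 * 32), 32, 32)
  expect_equal(denoiseBilateral(m, 1.5, 0.2), bilateralOracle(m, 1.5, 0.2),
               tolerance = 1e-10)
})

test_that("bilateral filter reduces speckle variance on flat bands", {
  worse <- 0
  for (i in 1:100) {
    s <- generatePhantom(smallPhantomConfig(fociCountMean = 0,
                                            confounderRate = 0,
                                            surfaceCurvature = 0),
                         seed = 2000 + i)
    row <- round(s@metadata$bounds[1, 32]) + 3
    band <- scanArray(s)[row + (0:2), ]
    flt <- denoiseBilateral(scanArray(s), 3, 0.1)[row + (0:2), ]
    if (var(as.vector(flt)) >= var(as.vector(band))) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("bilateral filter preserves an ideal step edge location", {
  m <- matrix(0.2, 32, 32); m[, 17:32] <- 0.7  # vertical step of height 0.5
  out <- denoiseBilateral(m, 2, 0.1)
  grad <- abs(out[, -1] - out[, -ncol(out)])
  edgeCols <- apply(grad, 1, which.max)
  expect_true(all(edgeCols == 16))
  # and the oracle agrees
  expect_equal(out, bilateralOracle(m, 2, 0.1), tolerance = 1e-10)
})

test_that("standardize hits the target geometry and keeps masks binary", {
  im <- matrix(runif(350 * 700), 350, 700)
  mk <- randomMask(350, 700, 10, seed = 1)
  z <- standardize(im, mk, 256L, 512L)
  expect_identical(dim(z$image), c(256L, 512L))
  expect_identical(dim(z$mask), c(256L, 512L))
  expect_true(all(z$mask %in% c(0, 1)))
  expect_true(all(z$image >= 0 & z$image <= 1))
})

test_that("standardize is the identity at the target size", {
  im <- matrix(runif(64 * 128), 64, 128)
  mk <- randomMask(64, 128, 4, seed = 2)
  z <- standardize(im, mk, 64L, 128L)
  expect_identical(z$image, im)
  expect_identical(z$mask, mk)
})

test_that("augmentation is deterministic and mask-safe", {
  s <- generatePhantom(smallPhantomConfig(), seed = 3)
  pol <- AugmentPolicy(hflipProb = 0.5, cropFraction = 0.7,
                       rotationMaxDeg = 25)
  a1 <- augmentSample(s, pol, seed = 11)
  a2 <- augmentSample(s, pol, seed = 11)
  expect_identical(scanArray(a1), scanArray(a2))
  expect_identical(maskArray(a1), maskArray(a2))
  expect_true(all(maskArray(a1) %in% c(0, 1)))
  expect_identical(dim(scanArray(a1)), dim(scanArray(s)))
})

test_that("horizontal flip is an involution and preserves component count", {
  s <- generatePhantom(smallPhantomConfig(), seed = 9)
  pol <- AugmentPolicy(hflipProb = 1, cropFraction = 1, rotationMaxDeg = 0)
  a <- augmentSample(s, pol, seed = 1)
  b <- augmentSample(a, pol, seed = 1)  # same draw: flip again
  expect_identical(maskArray(b), maskArray(s))
  expect_identical(scanArray(b), scanArray(s))
  expect_equal(max(floodFillLabel(maskArray(a))),
               max(floodFillLabel(maskArray(s))))
})

test_that("drawn rotation angles stay inside the configured range", {
  pol <- AugmentPolicy(rotationMaxDeg = 30)
  angles <- vapply(1:1000, function(i)
    HRFseg:::.augmentDraws(pol, i)$angle, 0)
  expect_gte(min(angles), 0)
  expect_lte(max(angles), 30)
  expect_gt(max(angles), 25)  # the sampler actually spans the range
  expect_lt(min(angles), 5)
})

test_that("rotated mask centroids match the analytic rotation within 1 px", {
  H <- 48L; W <- 48L
  mk <- matrix(0, H, W); mk[12:14, 30:32] <- 1  # one compact blob
  im <- matrix(0.3, H, W)
  for (ang in c(10, 22.5, 30)) {
    out <- HRFseg:::.applyAugment(im, mk, list(flip = FALSE, frac = 1,
                                               cy = 0, cx = 0, angle = ang))
    got <- which(out$mask == 1, arr.ind = TRUE)
    expect_gt(nrow(got), 0)
    gc <- colMeans(got)
    # analytic forward rotation of the source centroid about the centre
    th <- -ang * pi / 180  # inverse of the sampling map used by the kernel
    cy <- (H - 1) / 2 + 1; cx <- (W - 1) / 2 + 1
    src <- colMeans(which(mk == 1, arr.ind = TRUE))
    dy <- src[1] - cy; dx <- src[2] - cx
    exp_y <- cy + sin(th) * dx + cos(th) * dy
    exp_x <- cx + cos(th) * dx - sin(th) * dy
    expect_lt(abs(gc[1] - exp_y), 1)
    expect_lt(abs(gc[2] - exp_x), 1)
  }
})

test_that("image and mask round-trip through TIFF/PNG files", {
  s <- generatePhantom(smallPhantomConfig(), seed = 5)
  tf <- tempfile(fileext = ".tiff"); pf <- tempfile(fileext = ".png")
  writeScanTIFF(s@image, tf)
  writeMaskPNG(s@mask, pf)
  im <- readScanTIFF(tf)
  expect_lt(max(abs(im - scanArray(s))), 1 / 65535)  # 16-bit quantisation
  expect_identical(readMaskPNG(pf), maskArray(s))
})
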