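test_that("connected components handle singletons, diagonals and empty masks", {
  m <- matrix(0, 8, 8); m[3, 3] <- 1
  cc <- connectedComponents(m, 8L)
  expect_length(cc, 1)
  expect_equal(cc[[1]]$size, 1)

  d <- matrix(0, 8, 8); d[2, 2] <- 1; d[3, 3] <- 1
  expect_length(connectedComponents(d, 8L), 1)
  expect_length(connectedComponents(d, 4L), 2)

  expect_length(connectedComponents(matrix(0, 8, 8)), 0)
  expect_error(connectedComponents(matrix(0.5, 4, 4)), "binary")
  expect_error(connectedComponents(matrix(0, 4, 4), 6L), "connectivity")
})

test_that("component labelling agrees with the flood-fill oracle and EBImage", {
  for (seed in 1:25) {
    m <- randomMask(24, 40, sample(1:8, 1), seed = seed)
    for (conn in c(4L, 8L)) {
      lab <- HRFseg:::cpp_label_components(matrix(as.integer(m), 24), conn)
      oracle <- floodFillLabel(m, conn)
      expect_equal(max(lab), max(oracle))
      # same partition: labels agree up to renaming
      if (max(lab) > 0)
        expect_equal(length(unique(paste(lab[m == 1], oracle[m == 1]))),
                     max(lab))
    }
    # EBImage bwlabel is an independent 4-connectivity implementation
    expect_equal(max(HRFseg:::cpp_label_components(matrix(as.integer(m), 24), 4L)),
                 max(EBImage::bwlabel(m)))
  }
})

test_that("pixel metrics match direct formula evaluation", {
  # counts TP = 3, FP = 1, FN = 2 laid out on a strip
  pred <- matrix(c(1, 1, 1, 1, 0, 0, 0), 1)
  gt <- matrix(c(1, 1, 1, 0, 1, 1, 0), 1)
  m <- pixelMetrics(pred, gt)
  expect_equal(unname(m["se"]), 0.6)
  expect_equal(unname(m["p"]), 0.75)
  expect_equal(unname(m["dsc"]), 6 / 9, tolerance = 1e-12)

  t <- randomMask(16, 16, 3, seed = 21)
  expect_equal(unname(pixelMetrics(t, t)), c(1, 1, 1))

  empty <- matrix(0, 16, 16)
  m2 <- pixelMetrics(empty, t)
  expect_equal(unname(m2), c(0, 0, 0))
  expect_equal(unname(pixelMetrics(empty, empty)), c(1, 1, 1))
})

test_that("dice equals the harmonic mean of sensitivity and precision", {
  for (seed in 1:30) {
    pred <- randomMask(20, 20, sample(1:5, 1), seed = seed)
    gt <- randomMask(20, 20, sample(1:5, 1), seed = seed + 500)
    m <- pixelMetrics(pred, gt)
    if (m["se"] > 0 && m["p"] > 0)
      expect_equal(unname(m["dsc"]),
                   2 * m[["se"]] * m[["p"]] / (m[["se"]] + m[["p"]]),
                   tolerance = 1e-12)
  }
})

test_that("lesion matching applies the 60% coverage rule", {
  # one GT lesion fully covered
  gt <- matrix(0, 16, 16); gt[4:6, 4:6] <- 1
  pred <- gt
  lm <- lesionMatch(pred, gt, tau = 0.6)
  expect_equal(unname(confusionVector(lm$counts)[c("tp", "fp", "fn")]),
               c(1, 0, 0))

  # 10-pixel GT lesion with exactly 5 covered: coverage 0.5 < 0.6 ->
  # FN, and the overlapping prediction is an unmatched component -> FP
  gt2 <- matrix(0, 16, 16); gt2[8, 4:13] <- 1
  pred2 <- matrix(0, 16, 16); pred2[8, 4:8] <- 1
  lm2 <- lesionMatch(pred2, gt2, tau = 0.6)
  expect_equal(unname(lm2$coverage), 0.5)
  expect_equal(unname(confusionVector(lm2$counts)[c("tp", "fp", "fn")]),
               c(0, 1, 1))

  # disjoint predicted blob increments FP
  pred3 <- matrix(0, 16, 16); pred3[14, 14] <- 1
  lm3 <- lesionMatch(pred3, gt2, tau = 0.6)
  expect_equal(unname(confusionVector(lm3$counts)[c("tp", "fp", "fn")]),
               c(0, 1, 1))

  expect_error(lesionMatch(pred3, gt2, tau = 0), "tau")
  expect_error(lesionMatch(pred3, gt2, tau = 1.2), "tau")
})

test_that("lesion counts agree with the brute-force oracle on random pairs", {
  for (seed in 1:40) {
    pred <- randomMask(32, 64, sample(0:6, 1), seed = seed)
    gt <- randomMask(32, 64, sample(1:6, 1), seed = seed + 900)
    for (tau in c(0.4, 0.6)) for (conn in c(4L, 8L)) {
      got <- lesionMatch(pred, gt, tau, conn)
      want <- lesionCountsOracle(pred, gt, tau, conn)
      expect_equal(unname(confusionVector(got$counts)["tp"]), want$tp)
      expect_equal(unname(confusionVector(got$counts)["fn"]), want$fn)
      expect_equal(unname(confusionVector(got$counts)["fp"]), want$fp)
      expect_equal(unname(got$coverage), unname(want$coverage))
    }
  }
})

test_that("tau near zero marks any touched ground-truth lesion as detected", {
  for (seed in 1:15) {
    pred <- randomMask(24, 32, sample(1:5, 1), seed = seed)
    gt <- randomMask(24, 32, sample(1:5, 1), seed = seed + 321)
    got <- lesionMatch(pred, gt, tau = 1e-9)
    oracle <- lesionCountsOracle(pred, gt, 1e-9)
    touched <- sum(oracle$coverage > 0)
    expect_equal(unname(confusionVector(got$counts)["tp"]), touched)
  }
})

test_that("lesion tallies are anchored to component counts", {
  for (seed in 1:15) {
    pred <- randomMask(24, 32, sample(0:5, 1), seed = seed + 50)
    gt <- randomMask(24, 32, sample(1:5, 1), seed = seed + 1234)
    got <- confusionVector(lesionMatch(pred, gt)$counts)
    expect_equal(unname(got["tp"] + got["fn"]),
                 length(connectedComponents(gt)))
    expect_lte(got["fp"], length(connectedComponents(pred)))
  }
})

test_that("metrics are invariant under simultaneous horizontal flips", {
  pred <- randomMask(16, 24, 4, seed = 77)
  gt <- randomMask(16, 24, 4, seed = 78)
  fl <- function(m) m[, ncol(m):1]
  expect_equal(pixelMetrics(fl(pred), fl(gt)), pixelMetrics(pred, gt))
  expect_equal(lesionMatch(fl(pred), fl(gt))$metrics,
               lesionMatch(pred, gt)$metrics)
})

test_that("dataset evaluation macro-averages per-image metrics", {
  gt1 <- matrix(0, 16, 16); gt1[4:5, 4:5] <- 1
  pr1 <- gt1
  gt2 <- matrix(0, 16, 16); gt2[10, 10:13] <- 1
  pr2 <- matrix(0, 16, 16); pr2[10, 10] <- 1  # partial overlap
  rep <- evaluateDataset(list(pr1, pr2), list(gt1, gt2))
  per <- perImageMetrics(rep)
  expect_equal(rep@nImages, 2L)
  expect_equal(unname(pixelSummary(rep)["dsc"]), mean(per$pixel_dsc))
  expect_equal(unname(lesionSummary(rep)["se"]), mean(per$lesion_se))
  expect_equal(per$pixel_dsc[1], 1)
  # empty/empty convention scores (1, 1, 1) in both tiers
  e <- matrix(0, 16, 16)
  rep2 <- evaluateDataset(list(e), list(e))
  expect_equal(unname(pixelSummary(rep2)), c(1, 1, 1))
  expect_equal(unname(lesionSummary(rep2)), c(1, 1, 1))
  # single image: report equals that image's metrics
  rep3 <- evaluateDataset(list(pr2), list(gt2))
  expect_equal(unname(pixelSummary(rep3)),
               unname(pixelMetrics(pr2, gt2)))
  expect_error(evaluateDataset(list(pr1), list(gt1, gt2)), "length")
})
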