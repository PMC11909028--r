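# Closed-form oracle values, computed by hand from the definitions:
#   focal, single pixel at p_t = 0.5, alpha = 1 -> (would need alpha = 1,
#   checked through the unweighted identity below), gamma = 0 -> ln 2.
#   focal, single pixel p_t = 0.9, alpha = 0.25, gamma = 2:
#     0.25 * (1 - 0.9)^2 * (-log(0.9)) = 0.25 * 0.01 * 0.1053605...
#   dice on counts TP = 2, FP = 2, FN = 2: 1 - 2*2/(2*2+2+2) = 0.5.

test_that("focal loss matches closed-form arithmetic on single pixels", {
  # alpha ~ 1 is excluded by the config domain, so recover the ln 2 case
  # from the alpha-weighted value: loss = alpha * (1-p)^g * (-log p).
  cfgHalf <- LossConfig(alpha = 0.5, gamma = 0)
  got <- focalLoss(matrix(0.5), matrix(1), cfgHalf)
  expect_equal(got / 0.5, log(2), tolerance = 1e-6)

  cfg <- LossConfig(alpha = 0.25, gamma = 2)
  got2 <- focalLoss(matrix(0.9), matrix(1), cfg)
  expect_equal(got2, 0.25 * 0.01 * -log(0.9), tolerance = 1e-9)
  expect_lt(abs(got2 - 2.6341e-4), 1e-6)
})

test_that("focal loss vanishes on perfect predictions and weights background by 1 - alpha", {
  t <- randomMask(16, 16, 3, seed = 4)
  expect_lt(focalLoss(t, t, LossConfig(gamma = 2)), 1e-5)
  # single background pixel predicted at 0.5: weight must be 1 - alpha
  cfg <- LossConfig(alpha = 0.25, gamma = 0)
  expect_equal(focalLoss(matrix(0.5), matrix(0), cfg), 0.75 * log(2),
               tolerance = 1e-9)
})

test_that("dice loss matches count-based arithmetic", {
  # TP = 2, FP = 2, FN = 2 on a 1 x 6 strip
  pred <- matrix(c(1, 1, 1, 1, 0, 0), 1)
  gt <- matrix(c(1, 1, 0, 0, 1, 1), 1)
  expect_equal(diceLoss(pred, gt), 0.5, tolerance = 1e-6)
  # perfect overlap and disjoint masks
  m <- randomMask(16, 16, 3, seed = 5)
  expect_lt(diceLoss(m, m), 1e-5)
  disj <- matrix(0, 16, 16); disj[1, 1] <- 1
  m2 <- matrix(0, 16, 16); m2[16, 16] <- 1
  expect_gt(diceLoss(disj, m2), 1 - 1e-5)
})

test_that("combined loss is the stated convex combination", {
  pred <- matrix(c(1, 1, 1, 1, 0, 0), 1)
  gt <- matrix(c(1, 1, 0, 0, 1, 1), 1)
  cfg <- LossConfig()
  expect_equal(combinedLoss(pred, gt, cfg),
               0.5 * diceLoss(pred, gt, cfg) + 0.5 * focalLoss(pred, gt, cfg),
               tolerance = 1e-12)
  # fully disjoint binary masks: dice -> 1, focal at the clamp value
  p <- matrix(0, 8, 8); p[1, 1] <- 1
  g <- matrix(0, 8, 8); g[8, 8] <- 1
  cl <- 1e-7
  nWrong <- 2; n <- 64
  focalHand <- (0.25 * (1 - cl)^2 * -log(cl) +        # missed foreground
                0.75 * (1 - cl)^2 * -log(cl)) / n     # false foreground
  handTotal <- 0.5 * diceLoss(p, g, cfg) + 0.5 * focalHand
  expect_equal(combinedLoss(p, g, cfg), handTotal, tolerance = 1e-9)
  expect_gt(combinedLoss(p, g, cfg), 0.5)
})

test_that("loss weights must form a convex combination", {
  expect_error(LossConfig(weights = c(0.6, 0.6)), "sum")
  expect_error(LossConfig(weights = c(1, 1)), "sum")
  expect_silent(LossConfig(weights = c(0.7, 0.3)))
})

test_that("losses are permutation and translation invariant", {
  set.seed(11)
  p <- matrix(runif(64), 8, 8)
  t <- randomMask(8, 8, 2, seed = 6)
  cfg <- LossConfig()
  perm <- sample(64)
  pp <- matrix(p[perm], 8, 8); tt <- matrix(t[perm], 8, 8)
  expect_equal(focalLoss(pp, tt, cfg), focalLoss(p, t, cfg), tolerance = 1e-12)
  expect_equal(diceLoss(pp, tt, cfg), diceLoss(p, t, cfg), tolerance = 1e-12)
  # translation: shift both one column with wraparound
  ps <- p[, c(8, 1:7)]; ts <- t[, c(8, 1:7)]
  expect_equal(combinedLoss(ps, ts, cfg), combinedLoss(p, t, cfg),
               tolerance = 1e-12)
})

test_that("loss ranges and monotonicity on a true-positive pixel", {
  set.seed(12)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  t <- randomMask(8, 8, 2, seed = 7)
  t[3, 3] <- 1
  cfg <- LossConfig()
  expect_gte(diceLoss(p, t, cfg), 0); expect_lte(diceLoss(p, t, cfg), 1)
  expect_gte(focalLoss(p, t, cfg), 0)
  for (v in seq(0.1, 0.9, by = 0.2)) {
    p1 <- p; p1[3, 3] <- v
    p2 <- p; p2[3, 3] <- v + 0.05
    expect_lte(focalLoss(p2, t, cfg), focalLoss(p1, t, cfg) + 1e-12)
    expect_lte(diceLoss(p2, t, cfg), diceLoss(p1, t, cfg) + 1e-12)
  }
})

test_that("gradient of the combined loss is finite on clamped inputs", {
  set.seed(13)
  p <- matrix(runif(64, 0, 1), 8, 8)
  p[1, 1] <- 0; p[2, 2] <- 1  # exact endpoints must be clamped
  t <- randomMask(8, 8, 2, seed = 8)
  g <- HRFseg:::.combinedLossGrad(p, t, LossConfig())
  expect_true(all(is.finite(g)))
  # and it matches finite differences at an interior pixel
  cfg <- LossConfig()
  h <- 1e-6
  p1 <- p; p1[4, 4] <- p[4, 4] + h
  p2 <- p; p2[4, 4] <- p[4, 4] - h
  fd <- (combinedLoss(p1, t, cfg) - combinedLoss(p2, t, cfg)) / (2 * h)
  expect_equal(g[4, 4], fd, tolerance = 1e-4)
})

test_that("shape mismatches are rejected", {
  expect_error(focalLoss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
  expect_error(diceLoss(matrix(0.5, 2, 2), matrix(1, 2, 3)), "shape")
})
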