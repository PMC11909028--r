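# Shared fixtures and independent oracles used across the suite.

# Small phantom configuration: cheap to generate, realistic structure.
smallPhantomConfig <- function(...) {
  args <- utils::modifyList(
    list(height = 32L, width = 64L, nLayers = 3L,
         layerIntensities = c(0.2, 0.5, 0.3), surfaceCurvature = 2,
         fociCountMean = 4, fociDiameterRange = c(2, 4),
         confounderRate = 0.3),
    list(...))
  do.call(PhantomConfig, args)
}

# Independent connected-component oracle: recursive flood fill over an
# explicit stack, written without reference to the package labeller.
floodFillLabel <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (connectivity == 8L) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (x in seq_len(W)) for (y in seq_len(H)) {
    if (mask[y, x] == 0 || lab[y, x] != 0L) next
    cur <- cur + 1L
    stack <- list(c(y, x)); lab[y, x] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        ay <- p[1] + nb[k, 1]; ax <- p[2] + nb[k, 2]
        if (ay >= 1 && ay <= H && ax >= 1 && ax <= W &&
            mask[ay, ax] == 1 && lab[ay, ax] == 0L) {
          lab[ay, ax] <- cur
          stack[[length(stack) + 1L]] <- c(ay, ax)
        }
      }
    }
  }
  lab
}

# Brute-force lesion-level counting oracle built directly on the flood
# fill above and the coverage definition.
lesionCountsOracle <- function(pred, gt, tau, connectivity = 8L) {
  lg <- floodFillLabel(gt, connectivity)
  lp <- floodFillLabel(pred, connectivity)
  ng <- max(lg); np <- max(lp)
  cov <- if (ng > 0) vapply(seq_len(ng), function(i) {
    px <- lg == i
    sum(pred[px]) / sum(px)
  }, 0) else numeric(0)
  tpFlag <- cov >= tau
  det <- matrix(FALSE, nrow(gt), ncol(gt))
  for (i in which(tpFlag)) det <- det | (lg == i)
  fp <- if (np > 0) sum(vapply(seq_len(np), function(j)
    !any(det[lp == j]), TRUE)) else 0
  list(tp = sum(tpFlag), fn = ng - sum(tpFlag), fp = fp, coverage = cov)
}

# Dense brute-force bilateral filter for small images.
bilateralOracle <- function(x, sigmaS, sigmaR) {
  H <- nrow(x); W <- ncol(x)
  r <- max(1L, ceiling(3 * sigmaS))
  out <- matrix(0, H, W)
  for (xx in seq_len(W)) for (yy in seq_len(H)) {
    acc <- 0; wacc <- 0
    for (ax in max(1, xx - r):min(W, xx + r))
      for (ay in max(1, yy - r):min(H, yy + r)) {
        w <- exp(-((ax - xx)^2 + (ay - yy)^2) / (2 * sigmaS^2)) *
             exp(-(x[ay, ax] - x[yy, xx])^2 / (2 * sigmaR^2))
        acc <- acc + w * x[ay, ax]; wacc <- wacc + w
      }
    out[yy, xx] <- acc / wacc
  }
  out
}

# Random binary mask with a controlled number of small blobs.
randomMask <- function(H, W, nBlobs, seed) {
  set.seed(seed)
  m <- matrix(0, H, W)
  for (i in seq_len(nBlobs)) {
    cy <- sample(2:(H - 1), 1); cx <- sample(2:(W - 1), 1)
    r <- runif(1, 0.8, 2.2)
    ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
    xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
    for (ax in xs) for (ay in ys)
      if ((ay - cy)^2 + (ax - cx)^2 <= r^2) m[ay, ax] <- 1
  }
  m
}

# A deterministic mini dataset of denoised phantoms keyed by seed.
phantomSet <- function(n, seedBase = 100L, denoise = TRUE) {
  lapply(seq_len(n), function(i) {
    s <- generatePhantom(smallPhantomConfig(), seed = seedBase + i,
                         patientId = sprintf("P%03d", i), sliceId = "S1")
    if (!denoise) return(s)
    im <- denoiseBilateral(scanArray(s), 2, 0.15)
    PhantomSample(BScan(im, patientId(s), sliceId(s)), s@mask)
  })
}
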