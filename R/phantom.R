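#' @include AllClasses.R
NULL

# Smooth band geometry for one "patient": boundaries of nLayers bands as a
# (nLayers+1) x width matrix of row coordinates, deformed by a random sum
# of low-frequency sinusoids of amplitude `surfaceCurvature`.  Drawn from
# the current RNG stream.
.drawBandGeometry <- function(config) {
  H <- config@height; W <- config@width; nl <- config@nLayers
  x <- seq(0, 1, length.out = W)
  curve <- config@surfaceCurvature *
    (0.6 * sin(2 * pi * (runif(1, 0.5, 1.5) * x + runif(1))) +
     0.4 * sin(2 * pi * (runif(1, 1.5, 2.5) * x + runif(1))))
  top <- 0.22 * H + curve
  bottom <- 0.78 * H + curve * runif(1, 0.6, 1)
  w <- runif(nl, 0.5, 1.5); w <- w / sum(w)
  bounds <- matrix(0, nl + 1L, W)
  bounds[1L, ] <- top
  for (l in seq_len(nl)) bounds[l + 1L, ] <- bounds[l, ] + w[l] * (bottom - top)
  .clamp(bounds, 1, H - 1)
}

# Paint layered bands onto an H x W canvas; background (vitreous/choroid)
# stays dark.
.renderBands <- function(config, bounds) {
  H <- config@height; W <- config@width
  img <- matrix(0.03, H, W)
  y <- matrix(seq_len(H), H, W)
  for (l in seq_len(config@nLayers)) {
    b0 <- matrix(bounds[l, ], H, W, byrow = TRUE)
    b1 <- matrix(bounds[l + 1L, ], H, W, byrow = TRUE)
    img[y >= b0 & y < b1] <- config@layerIntensities[l]
  }
  img
}

# Footprint of a filled ellipse with centre (cy, cx), major diameter d,
# axis ratio `ratio` in [0.7, 1] and orientation theta; returns an index
# matrix of (row, col) pixels inside the image.
.ellipsePixels <- function(cy, cx, d, ratio, theta, H, W) {
  a <- d / 2; b <- ratio * d / 2
  r <- ceiling(a) + 1L
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  gy <- rep(ys, times = length(xs)) - cy
  gx <- rep(xs, each = length(ys)) - cx
  u <- (gx * cos(theta) + gy * sin(theta)) / a
  v <- (-gx * sin(theta) + gy * cos(theta)) / b
  keep <- u * u + v * v <= 1
  cbind(rep(ys, times = length(xs))[keep], rep(xs, each = length(ys))[keep])
}

# Sample non-overlapping focus parameters strictly inside the banded
# region.  Returns a list of lists (cy, cx, d, ratio, theta).
.sampleFoci <- function(k, config, bounds) {
  H <- config@height; W <- config@width
  dr <- config@fociDiameterRange
  out <- list()
  if (k == 0L) return(out)
  centres <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  for (i in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      d <- runif(1, dr[1], dr[2])
      r <- d / 2
      cx <- runif(1, 1 + r, W - r)
      xi <- .clamp(round(cx), 1, W)
      ylo <- bounds[1L, xi] + r + 1
      yhi <- bounds[nrow(bounds), xi] - r - 1
      if (yhi <= ylo) next
      cy <- runif(1, ylo, yhi)
      if (nrow(centres) > 0) {
        dd <- sqrt((centres[, 1] - cy)^2 + (centres[, 2] - cx)^2)
        if (any(dd < radii + r + 2)) next
      }
      centres <- rbind(centres, c(cy, cx)); radii <- c(radii, r)
      out[[length(out) + 1L]] <- list(cy = cy, cx = cx, d = d,
                                      ratio = runif(1, 0.7, 1),
                                      theta = runif(1, 0, pi))
      placed <- TRUE
      break
    }
    if (!placed) break  # region saturated; keep what fitted
  }
  out
}

#' Generate one synthetic OCT B-scan with ground-truth HRF mask
#'
#' Renders \code{nLayers} horizontal retinal bands deformed by a smooth
#' curve, adds bright elliptical punctate foci (the HRF analogue) strictly
#' inside the banded region, optionally adds larger exudate-like
#' confounder blobs that cast a darker back-shadow column (and are
#' excluded from the mask), and finally applies unit-mean multiplicative
#' gamma speckle.  Identical (config, seed) pairs produce bit-identical
#' output.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param seed integer seed; defaults to \code{config@seed}.
#' @param patientId,sliceId identifiers stored on the output.
#' @param geometry optional precomputed band-boundary matrix (used by
#'   \code{\link{generateDataset}} to share layer geometry within a
#'   patient).
#' @return A \linkS4class{PhantomSample}; \code{metadata} holds the band
#'   boundaries, the drawn focus count and the confounder footprint.
#' @examples
#' cfg <- PhantomConfig(height = 64, width = 128, fociCountMean = 4,
#'                      surfaceCurvature = 4)
#' s <- generatePhantom(cfg, seed = 7)
#' sum(maskArray(s))  # foreground pixels
#' @export
generatePhantom <- function(config, seed = config@seed, patientId = "P1",
                            sliceId = "S1", geometry = NULL) {
  validObject(config)
  H <- config@height; W <- config@width
  .withSeed(seed, {
    bounds <- if (is.null(geometry)) .drawBandGeometry(config) else geometry
    img <- .renderBands(config, bounds)

    bandArea <- sum(pmax(bounds[nrow(bounds), ] - bounds[1L, ], 0))
    dr <- config@fociDiameterRange
    expArea <- config@fociCountMean * pi * mean(c(dr[1], dr[2]) / 2)^2 * 0.85
    if (expArea > 0.25 * bandArea)
      stop("expected focus area exceeds 25% of the banded region; ",
           "foci must stay small and punctate", call. = FALSE)

    mask <- matrix(0, H, W)
    k <- rpois(1L, config@fociCountMean)
    foci <- .sampleFoci(k, config, bounds)
    for (f in foci) {
      px <- .ellipsePixels(f$cy, f$cx, f$d, f$ratio, f$theta, H, W)
      if (nrow(px) == 0L) next
      img[px] <- .clamp(img[px] + config@fociContrast, 0, 1)
      mask[px] <- 1
    }

    confFoot <- matrix(0, H, W)
    m <- rpois(1L, config@confounderRate)
    if (m > 0L) for (i in seq_len(m)) {
      for (try in seq_len(100L)) {
        d <- runif(1, 8, 16)
        cx <- runif(1, 1 + d / 2, W - d / 2)
        xi <- .clamp(round(cx), 1, W)
        ylo <- bounds[1L, xi] + d / 2 + 1
        yhi <- bounds[nrow(bounds), xi] - d / 2 - 1
        if (yhi <= ylo) next
        cy <- runif(1, ylo, yhi)
        px <- .ellipsePixels(cy, cx, d, runif(1, 0.7, 1), runif(1, 0, pi), H, W)
        if (nrow(px) == 0L || any(mask[px] == 1)) next
        img[px] <- .clamp(img[px] + 0.3, 0, 1)
        confFoot[px] <- 1
        # back-shadow: darken the strip below the blob, a hallmark of hard
        # exudates that true HRF lack
        xs <- sort(unique(px[, 2]))
        for (xc in xs) {
          y0 <- max(px[px[, 2] == xc, 1]) + 1L
          if (y0 <= H) img[y0:H, xc] <- img[y0:H, xc] * 0.55
        }
        break
      }
    }

    speckle <- matrix(rgamma(H * W, shape = config@speckleShape,
                             rate = config@speckleShape), H, W)
    img <- .clamp(img * speckle, 0, 1)

    PhantomSample(BScan(img, patientId, sliceId), MaskImage(mask),
                  metadata = list(bounds = bounds, fociCount = length(foci),
                                  confounder = confFoot, seed = seed))
  })
}

#' Generate a multi-patient phantom dataset
#'
#' Samples sharing a patient share the band-boundary geometry (as real
#' B-scans from one eye would) but differ in focus placement, confounders
#' and speckle.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param nPatients,slicesPerPatient dataset layout.
#' @param seed master seed; per-patient and per-slice seeds are derived
#'   deterministically from it.
#' @param totalSlices optional total to thin down to (dropping random
#'   slices while keeping at least one per patient), e.g. 50 patients x 4
#'   slices thinned to 173 to emulate a typical clinical corpus.
#' @return List of \linkS4class{PhantomSample}; sample ids are
#'   "P<i>_S<j>".
#' @export
generateDataset <- function(config, nPatients, slicesPerPatient,
                            seed = config@seed, totalSlices = NULL) {
  stopifnot(nPatients >= 1L, slicesPerPatient >= 1L)
  validObject(config)
  samples <- list()
  for (p in seq_len(nPatients)) {
    geom <- .withSeed(.deriveSeed(seed, p, 0L), .drawBandGeometry(config))
    for (s in seq_len(slicesPerPatient)) {
      sm <- generatePhantom(config, seed = .deriveSeed(seed, p, s),
                            patientId = sprintf("P%03d", p),
                            sliceId = sprintf("S%02d", s), geometry = geom)
      samples[[length(samples) + 1L]] <- sm
    }
  }
  if (!is.null(totalSlices)) {
    n <- length(samples)
    if (totalSlices > n) stop("totalSlices exceeds generated count")
    if (totalSlices < n) {
      pid <- vapply(samples, patientId, "")
      keepOne <- vapply(split(seq_len(n), pid), `[`, 0L, 1L)
      pool <- setdiff(seq_len(n), keepOne)
      drop <- .withSeed(.deriveSeed(seed, 999983L),
                        sample(pool, n - totalSlices))
      samples <- samples[-drop]
    }
  }
  samples
}

#' Sample identifier ("<patient>_<slice>")
#' @param sample a \linkS4class{PhantomSample}.
#' @return character scalar.
#' @export
sampleId <- function(sample) paste0(patientId(sample), "_", sliceId(sample))
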