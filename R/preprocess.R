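#' @include AllClasses.R
NULL

#' Edge-preserving bilateral denoising
#'
#' Applies the standard bilateral filter (joint Gaussian kernel in space
#' and intensity, weights normalised per pixel) to suppress the
#' multiplicative speckle characteristic of OCT while preserving band
#' edges and the small bright foci that must survive denoising.
#'
#' @param image a \linkS4class{BScan} or numeric matrix in [0, 1].
#' @param sigmaSpatial spatial standard deviation in pixels (> 0); the
#'   default 3 preserves 2-6 px foci while smoothing speckle.
#' @param sigmaRange intensity standard deviation in gray units (> 0).
#' @return Same type as the input, filtered; values remain in [0, 1].
#' @export
denoiseBilateral <- function(image, sigmaSpatial = 3, sigmaRange = 0.1) {
  if (sigmaSpatial <= 0 || sigmaRange <= 0)
    stop("sigmaSpatial and sigmaRange must be positive", call. = FALSE)
  m <- if (is(image, "BScan")) image@pixels else image
  out <- cpp_bilateral(m, sigmaSpatial, sigmaRange)
  out <- .clamp(out, 0, 1)
  if (is(image, "BScan")) BScan(out, image@patientId, image@sliceId) else out
}

#' Resize an image/mask pair to the working resolution
#'
#' Image is resized with bilinear interpolation, the mask with
#' nearest-neighbour (then re-binarised), so the mask stays strictly
#' binary.  An input already at the target size is returned unchanged.
#'
#' @param image a \linkS4class{BScan} or matrix.
#' @param mask the aligned \linkS4class{MaskImage} or binary matrix
#'   (may be NULL).
#' @param targetH,targetW target size in pixels (>= 32); the defaults
#'   256 x 512 are the working resolution for 350 x 700 scans.
#' @return list(image, mask) at the target size.
#' @export
standardize <- function(image, mask = NULL, targetH = 256L, targetW = 512L) {
  if (targetH < 32L || targetW < 32L)
    stop("target size must be at least 32 x 32", call. = FALSE)
  im <- if (is(image, "BScan")) image@pixels else image
  mk <- if (is(mask, "MaskImage")) mask@pixels else mask
  if (nrow(im) != targetH || ncol(im) != targetW) {
    im <- .clamp(EBImage::resize(im, w = targetH, h = targetW,
                                 filter = "bilinear"), 0, 1)
    im <- matrix(as.numeric(im), targetH, targetW)
  }
  if (!is.null(mk) && (nrow(mk) != targetH || ncol(mk) != targetW)) {
    mk <- EBImage::resize(mk, w = targetH, h = targetW, filter = "none")
    mk <- matrix(as.numeric(mk > 0.5), targetH, targetW)
  }
  outImage <- if (is(image, "BScan"))
    BScan(im, image@patientId, image@sliceId) else im
  outMask <- if (is.null(mk)) NULL
    else if (is(mask, "MaskImage")) MaskImage(mk) else mk
  list(image = outImage, mask = outMask)
}

# The three augmentation draws for a given (policy, seed); exposed
# internally so the sampler can be tested in isolation.
.augmentDraws <- function(policy, seed) {
  .withSeed(seed, list(
    flip = runif(1) < policy@hflipProb,
    frac = runif(1, policy@cropFraction, 1),
    cy = runif(1), cx = runif(1),
    angle = runif(1, 0, policy@rotationMaxDeg)))
}

# Apply one geometric transform set to an (image, mask) matrix pair.
.applyAugment <- function(im, mk, draws) {
  H <- nrow(im); W <- ncol(im)
  if (draws$flip) {
    im <- im[, W:1, drop = FALSE]
    mk <- mk[, W:1, drop = FALSE]
  }
  if (draws$frac < 1) {
    s <- sqrt(draws$frac)
    h2 <- max(16L, round(H * s)); w2 <- max(16L, round(W * s))
    y0 <- 1L + floor(draws$cy * (H - h2)); x0 <- 1L + floor(draws$cx * (W - w2))
    im <- im[y0:(y0 + h2 - 1L), x0:(x0 + w2 - 1L), drop = FALSE]
    mk <- mk[y0:(y0 + h2 - 1L), x0:(x0 + w2 - 1L), drop = FALSE]
    im <- .asMatrix(cpp_resize_bilinear(.asChannel(im), H, W))
    mk <- cpp_resize_nearest(mk, H, W)
  }
  if (draws$angle > 0) {
    bg <- median(im[im <= quantile(im, 0.5)])  # background fill level
    im <- cpp_rotate(im, draws$angle, "bilinear", bg)
    mk <- cpp_rotate(mk, draws$angle, "nearest", 0)
  }
  list(image = .clamp(im, 0, 1), mask = round(mk))
}

#' Random geometric augmentation of an image/mask pair
#'
#' Horizontal flip (probability \code{hflipProb}), random crop retaining a
#' uniform fraction of area in [cropFraction, 1] followed by resize back
#' to the input shape, and rotation by a uniform angle in
#' [0, rotationMaxDeg] degrees about the image centre.  Image and mask
#' receive the identical transform; the image is interpolated bilinearly
#' (rotation corners filled with the background median), the mask with
#' nearest-neighbour (corners filled with 0) so it stays binary.
#' Deterministic under (sample, policy, seed).
#'
#' @param sample a \linkS4class{PhantomSample}.
#' @param policy an \linkS4class{AugmentPolicy}.
#' @param seed integer seed; defaults to \code{policy@seed}.
#' @return The augmented \linkS4class{PhantomSample}.
#' @export
augmentSample <- function(sample, policy, seed = policy@seed) {
  validObject(policy)
  draws <- .augmentDraws(policy, seed)
  out <- .applyAugment(scanArray(sample), maskArray(sample), draws)
  PhantomSample(BScan(out$image, patientId(sample), sliceId(sample)),
                MaskImage(out$mask), metadata = sample@metadata)
}

# ------------------------------------------------------------------ file IO

#' Read / write B-scans and masks
#'
#' Images are stored as 16-bit grayscale TIFF, masks as 8-bit 0/255 PNG
#' (thresholded at 128 on read).
#'
#' @param path file path.
#' @param image,mask objects to write.
#' @name image-io
NULL

#' @rdname image-io
#' @export
writeScanTIFF <- function(image, path) {
  m <- if (is(image, "BScan")) image@pixels else image
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname image-io
#' @export
readScanTIFF <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}

#' @rdname image-io
#' @export
writeMaskPNG <- function(mask, path) {
  m <- if (is(mask, "MaskImage")) mask@pixels else mask
  png::writePNG(m, path)  # 0/1 doubles -> 0/255 8-bit
  invisible(path)
}

#' @rdname image-io
#' @export
readMaskPNG <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.numeric(m >= 128 / 255), nrow(m), ncol(m))
}
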