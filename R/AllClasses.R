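#' @include utils.R
NULL

# ---------------------------------------------------------------- containers

#' OCT B-scan container
#'
#' A single grayscale OCT B-scan: a 2D grid of intensities in [0, 1] with
#' patient and slice identity.  Rows are depth (axial), columns lateral.
#'
#' @slot pixels numeric matrix of intensities in [0, 1].
#' @slot patientId,sliceId character scalars identifying the source.
#' @export
setClass("BScan",
  representation(pixels = "matrix", patientId = "character",
                 sliceId = "character"),
  prototype(patientId = "NA", sliceId = "NA"))

setValidity("BScan", function(object) {
  p <- object@pixels
  if (nrow(p) < 32L || ncol(p) < 32L)
    return("B-scan must be at least 32 x 32 pixels")
  if (anyNA(p) || min(p) < 0 || max(p) > 1)
    return("intensities must lie in [0, 1]")
  TRUE
})

#' @param pixels numeric matrix in [0, 1].
#' @param patientId,sliceId identifiers.
#' @return A \code{BScan} object.
#' @rdname BScan-class
#' @export
BScan <- function(pixels, patientId = "NA", sliceId = "NA") {
  new("BScan", pixels = pixels, patientId = as.character(patientId),
      sliceId = as.character(sliceId))
}

#' Binary lesion mask aligned with a B-scan
#'
#' @slot pixels matrix with values in {0, 1}; 1 marks HRF pixels.
#' @export
setClass("MaskImage", representation(pixels = "matrix"))

setValidity("MaskImage", function(object) {
  if (!all(object@pixels %in% c(0, 1))) return("mask values must be 0/1")
  TRUE
})

#' @param pixels binary matrix.
#' @return A \code{MaskImage} object.
#' @rdname MaskImage-class
#' @export
MaskImage <- function(pixels) {
  storage.mode(pixels) <- "double"
  new("MaskImage", pixels = pixels)
}

#' A phantom (or clinical) image/mask pair
#'
#' @slot image a \linkS4class{BScan}.
#' @slot mask the aligned \linkS4class{MaskImage}.
#' @slot metadata list of generator provenance (band boundaries, focus and
#'   confounder footprints), used by tests and diagnostics.
#' @export
setClass("PhantomSample",
  representation(image = "BScan", mask = "MaskImage", metadata = "list"),
  prototype(metadata = list()))

setValidity("PhantomSample", function(object) {
  di <- dim(object@image@pixels); dm <- dim(object@mask@pixels)
  if (!identical(di, dm)) return("image and mask dimensions differ")
  TRUE
})

#' @param image,mask the aligned pair.
#' @param patientId,sliceId identifiers (stored on the image).
#' @param metadata provenance list.
#' @return A \code{PhantomSample}.
#' @rdname PhantomSample-class
#' @export
PhantomSample <- function(image, mask, patientId = NULL, sliceId = NULL,
                          metadata = list()) {
  if (!is.null(patientId)) image@patientId <- as.character(patientId)
  if (!is.null(sliceId)) image@sliceId <- as.character(sliceId)
  new("PhantomSample", image = image, mask = mask, metadata = metadata)
}

# ------------------------------------------------------------ configurations

#' Phantom generator configuration
#'
#' Defines the synthetic OCT B-scan model: horizontally layered retinal
#' bands deformed by a smooth surface curve, multiplicative gamma speckle,
#' bright elliptical punctate foci (the HRF analogue, no back-shadow) and
#' optional larger exudate-like confounder blobs that cast a back-shadow
#' and are excluded from the truth mask.
#'
#' @slot height,width image size in pixels (>= 32).
#' @slot nLayers number of retinal bands (>= 2).
#' @slot layerIntensities mean gray level of each band, in [0, 1].
#' @slot surfaceCurvature amplitude (pixels) of the smooth vertical
#'   displacement of band boundaries.
#' @slot speckleShape shape parameter of the unit-mean multiplicative gamma
#'   speckle; smaller is noisier.
#' @slot fociCountMean expected HRF count per image (Poisson).
#' @slot fociDiameterRange min/max focus diameter in pixels; the default
#'   (2, 6) corresponds to 20-50 um lesions at typical lateral resolution.
#' @slot fociContrast additive brightness of a focus above its local band.
#' @slot confounderRate expected count of exudate-like blobs per image.
#' @slot seed default random seed.
#' @export
setClass("PhantomConfig",
  representation(height = "integer", width = "integer", nLayers = "integer",
    layerIntensities = "numeric", surfaceCurvature = "numeric",
    speckleShape = "numeric", fociCountMean = "numeric",
    fociDiameterRange = "numeric", fociContrast = "numeric",
    confounderRate = "numeric", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  if (object@height < 32L || object@width < 32L)
    return("height and width must be >= 32")
  if (object@nLayers < 2L) return("need at least 2 retinal bands")
  if (length(object@layerIntensities) != object@nLayers)
    return("layerIntensities must have one value per band")
  if (min(object@layerIntensities) < 0 || max(object@layerIntensities) > 1)
    return("layerIntensities must lie in [0, 1]")
  dr <- object@fociDiameterRange
  if (length(dr) != 2L || dr[1] < 1 || dr[2] < dr[1])
    return("fociDiameterRange must be (min, max) with min >= 1")
  if (dr[2] >= min(object@height, object@width) / 4)
    return("max focus diameter must stay below min(height, width)/4")
  if (object@fociContrast <= 0) return("fociContrast must be > 0")
  if (object@speckleShape <= 0) return("speckleShape must be > 0")
  if (object@fociCountMean < 0 || object@confounderRate < 0)
    return("rates must be nonnegative")
  TRUE
})

#' @param height,width,nLayers,layerIntensities,surfaceCurvature,speckleShape
#'   see slots.
#' @param fociCountMean,fociDiameterRange,fociContrast,confounderRate,seed
#'   see slots.
#' @return A \code{PhantomConfig}.
#' @rdname PhantomConfig-class
#' @export
PhantomConfig <- function(height = 350L, width = 700L, nLayers = 5L,
    layerIntensities = c(0.18, 0.5, 0.28, 0.6, 0.35),
    surfaceCurvature = 12, speckleShape = 4, fociCountMean = 8,
    fociDiameterRange = c(2, 6), fociContrast = 0.35,
    confounderRate = 0.5, seed = 1L) {
  new("PhantomConfig", height = as.integer(height), width = as.integer(width),
      nLayers = as.integer(nLayers), layerIntensities = layerIntensities,
      surfaceCurvature = surfaceCurvature, speckleShape = speckleShape,
      fociCountMean = fociCountMean, fociDiameterRange = fociDiameterRange,
      fociContrast = fociContrast, confounderRate = confounderRate,
      seed = as.integer(seed))
}

#' Geometric augmentation policy
#'
#' Horizontal flipping, random cropping (resized back to the working
#' resolution) and random rotation in [0, rotationMaxDeg] degrees; image
#' and mask always receive the identical transform.
#'
#' @slot hflipProb probability of a horizontal flip.
#' @slot cropFraction minimum fraction of area retained by the random crop,
#'   in (0, 1]; the drawn fraction is uniform between this and 1.
#' @slot rotationMaxDeg maximum rotation angle, in [0, 30] degrees.
#' @slot seed default seed.
#' @export
setClass("AugmentPolicy",
  representation(hflipProb = "numeric", cropFraction = "numeric",
                 rotationMaxDeg = "numeric", seed = "integer"))

setValidity("AugmentPolicy", function(object) {
  if (object@hflipProb < 0 || object@hflipProb > 1)
    return("hflipProb must be a probability")
  if (object@cropFraction <= 0 || object@cropFraction > 1)
    return("cropFraction must lie in (0, 1]")
  if (object@rotationMaxDeg < 0 || object@rotationMaxDeg > 30)
    return("rotationMaxDeg must lie in [0, 30]")
  TRUE
})

#' @param hflipProb,cropFraction,rotationMaxDeg,seed see slots.
#' @return An \code{AugmentPolicy}.
#' @rdname AugmentPolicy-class
#' @export
AugmentPolicy <- function(hflipProb = 0.5, cropFraction = 0.7,
                          rotationMaxDeg = 30, seed = 1L) {
  new("AugmentPolicy", hflipProb = hflipProb, cropFraction = cropFraction,
      rotationMaxDeg = rotationMaxDeg, seed = as.integer(seed))
}

#' Compound loss configuration
#'
#' Parameters of the dice + focal training objective.  \code{alpha}
#' balances positive against negative pixels in the focal term (background
#' pixels are weighted \code{1 - alpha}); \code{gamma} down-weights easy
#' pixels; \code{weights} mixes the two losses and must sum to one.
#'
#' @slot alpha focal class-balance weight in (0, 1).
#' @slot gamma focal focusing exponent >= 0.
#' @slot diceSmooth additive smoothing of the soft dice ratio.
#' @slot weights c(w_dice, w_focal), summing to 1.
#' @export
setClass("LossConfig",
  representation(alpha = "numeric", gamma = "numeric", diceSmooth = "numeric",
                 weights = "numeric"))

setValidity("LossConfig", function(object) {
  if (!is.finite(object@alpha) || object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie in (0, 1)")
  if (!is.finite(object@gamma) || object@gamma < 0)
    return("gamma must be >= 0")
  if (object@diceSmooth <= 0) return("diceSmooth must be positive")
  w <- object@weights
  if (length(w) != 2L || any(!is.finite(w)) || any(w < 0) ||
      abs(sum(w) - 1) > 1e-9)
    return("weights must be two nonnegative numbers summing to 1")
  TRUE
})

#' @param alpha,gamma,diceSmooth,weights see slots.
#' @return A \code{LossConfig}.
#' @rdname LossConfig-class
#' @export
LossConfig <- function(alpha = 0.25, gamma = 2, diceSmooth = 1e-6,
                       weights = c(0.5, 0.5)) {
  new("LossConfig", alpha = alpha, gamma = gamma, diceSmooth = diceSmooth,
      weights = weights)
}

#' Network architecture configuration
#'
#' The faithful configuration is a three-level U-Net branch and a two-level
#' over-complete Kite-Net branch fused by cross-attention blocks at the
#' pairings (kite level 1, U level 2) and (kite level 2, U level 3), i.e.
#' at spatial resample factors 4 and 16.  Paired levels must carry equal
#' channel counts.
#'
#' @slot uChannels channels of the three U-Net levels.
#' @slot kiteChannels channels of the two Kite-Net levels.
#' @slot cabPairings integer matrix, one row per (kite level, U level) pair.
#' @slot norm logical; per-channel (instance) normalisation inside blocks.
#' @slot mode "dual", "u_only" or "kite_only" (branch ablations).
#' @slot inputPolicy "reject" or "resize" when input size is not divisible
#'   by 4 (two poolings).
#' @export
setClass("ModelConfig",
  representation(uChannels = "integer", kiteChannels = "integer",
    cabPairings = "matrix", norm = "logical", mode = "character",
    inputPolicy = "character"))

setValidity("ModelConfig", function(object) {
  if (length(object@uChannels) != 3L) return("U branch must have 3 levels")
  if (length(object@kiteChannels) != 2L)
    return("Kite branch must have 2 levels")
  if (!object@mode %in% c("dual", "u_only", "kite_only"))
    return("mode must be dual, u_only or kite_only")
  if (!object@inputPolicy %in% c("reject", "resize"))
    return("inputPolicy must be reject or resize")
  p <- object@cabPairings
  if (ncol(p) != 2L) return("cabPairings must have two columns")
  for (i in seq_len(nrow(p))) {
    kc <- object@kiteChannels[p[i, 1]]
    uc <- object@uChannels[p[i, 2]]
    if (is.na(kc) || is.na(uc)) return("cabPairings index out of range")
    if (kc != uc)
      return(sprintf("paired levels must have equal channels (kite %d has %d, U %d has %d)",
                     p[i, 1], kc, p[i, 2], uc))
  }
  if (any(object@uChannels %% 2L != 0L) || any(object@kiteChannels %% 2L != 0L))
    return("channel counts must be even (cross-attention halves them)")
  TRUE
})

#' @param uChannels,kiteChannels,cabPairings,norm,mode,inputPolicy see slots.
#' @return A \code{ModelConfig}.
#' @rdname ModelConfig-class
#' @export
ModelConfig <- function(uChannels = c(8L, 16L, 32L),
    kiteChannels = c(16L, 32L),
    cabPairings = rbind(c(1L, 2L), c(2L, 3L)),
    norm = TRUE, mode = "dual", inputPolicy = "reject") {
  new("ModelConfig", uChannels = as.integer(uChannels),
      kiteChannels = as.integer(kiteChannels),
      cabPairings = matrix(as.integer(cabPairings), ncol = 2L),
      norm = norm, mode = mode, inputPolicy = inputPolicy)
}

#' Training configuration
#'
#' Adam at batch size one with plateau-based learning-rate halving and
#' early stopping.  Defaults: learning rate 1e-4, beta1 0.9, beta2 0.999,
#' 150 epochs, halve the learning rate after 5 epochs without improvement
#' of the monitored quantity, stop after \code{earlyStopPatience} epochs
#' without improvement.
#'
#' @slot lr,beta1,beta2 Adam parameters.
#' @slot epochs maximum number of epochs.
#' @slot batchSize images per update (1 in the faithful configuration).
#' @slot plateauPatience epochs without improvement before halving the lr.
#' @slot lrFactor multiplicative lr decay factor in (0, 1).
#' @slot earlyStopPatience epochs without improvement before stopping.
#' @slot monitor "val_loss", "train_loss" or "val_dsc".
#' @slot seed training seed (shuffling, augmentation, initialisation).
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", beta1 = "numeric", beta2 = "numeric",
    epochs = "integer", batchSize = "integer", plateauPatience = "integer",
    lrFactor = "numeric", earlyStopPatience = "integer",
    monitor = "character", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@lr <= 0) return("lr must be positive")
  if (object@lrFactor <= 0 || object@lrFactor >= 1)
    return("lrFactor must lie in (0, 1)")
  if (object@plateauPatience < 1L || object@earlyStopPatience < 1L)
    return("patience values must be >= 1")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (!object@monitor %in% c("val_loss", "train_loss", "val_dsc"))
    return("monitor must be val_loss, train_loss or val_dsc")
  TRUE
})

#' @param lr,beta1,beta2,epochs,batchSize,plateauPatience,lrFactor see slots.
#' @param earlyStopPatience,monitor,seed see slots.
#' @return A \code{TrainConfig}.
#' @rdname TrainConfig-class
#' @export
TrainConfig <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
    epochs = 150L, batchSize = 1L, plateauPatience = 5L, lrFactor = 0.5,
    earlyStopPatience = 15L, monitor = "val_loss", seed = 1L) {
  new("TrainConfig", lr = lr, beta1 = beta1, beta2 = beta2,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      plateauPatience = as.integer(plateauPatience), lrFactor = lrFactor,
      earlyStopPatience = as.integer(earlyStopPatience), monitor = monitor,
      seed = as.integer(seed))
}

# ------------------------------------------------------------------- results

#' Dataset split into train/validation/test
#'
#' @slot train,val,test disjoint character vectors of sample ids.
#' @slot grouped logical; TRUE if patients were kept within one subset.
#' @slot seed the shuffling seed.
#' @export
setClass("DatasetSplit",
  representation(train = "character", val = "character", test = "character",
                 grouped = "logical", seed = "integer"))

setValidity("DatasetSplit", function(object) {
  ids <- c(object@train, object@val, object@test)
  if (anyDuplicated(ids)) return("subsets must be pairwise disjoint")
  if (length(object@train) == 0L || length(object@val) == 0L ||
      length(object@test) == 0L)
    return("every subset must be nonempty")
  TRUE
})

#' Training history
#'
#' @slot records data.frame with one row per epoch: epoch, train_loss,
#'   val_loss, val_dsc, lr.
#' @slot stoppedEpoch the epoch at which training stopped.
#' @slot bestEpoch the epoch whose weights were returned.
#' @export
setClass("TrainHistory",
  representation(records = "data.frame", stoppedEpoch = "integer",
                 bestEpoch = "integer"))

setValidity("TrainHistory", function(object) {
  r <- object@records
  need <- c("epoch", "train_loss", "val_loss", "val_dsc", "lr")
  if (!all(need %in% names(r))) return("records lack required columns")
  if (nrow(r) > 1 && any(diff(r$lr) > 1e-15))
    return("learning rate must be non-increasing")
  TRUE
})

#' Fitted (or freshly initialised) segmentation model
#'
#' @slot config the \linkS4class{ModelConfig}.
#' @slot weights named list of parameter arrays.
#' @slot seed initialisation seed.
#' @export
setClass("HRFModel",
  representation(config = "ModelConfig", weights = "list", seed = "integer"))

#' Pixel/lesion confusion tallies
#'
#' At the pixel level tn completes the 2x2 table; at the lesion level tn is
#' the sentinel 0 (true-negative lesions are undefined).
#'
#' @slot tp,fp,fn,tn nonnegative counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 tn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(v < 0)) return("counts must be nonnegative")
  TRUE
})

#' @param tp,fp,fn,tn counts.
#' @return A \code{ConfusionCounts}.
#' @rdname ConfusionCounts-class
#' @export
ConfusionCounts <- function(tp = 0, fp = 0, fn = 0, tn = 0) {
  new("ConfusionCounts", tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Two-tier evaluation report
#'
#' Dataset-level values are unweighted means of the per-image values
#' (macro averaging).
#'
#' @slot pixel,lesion named numeric vectors (se, p, dsc) in [0, 1].
#' @slot perImage data.frame of per-image metrics.
#' @slot nImages number of images evaluated.
#' @slot tau,connectivity the lesion-matching parameters used.
#' @export
setClass("MetricsReport",
  representation(pixel = "numeric", lesion = "numeric",
                 perImage = "data.frame", nImages = "integer",
                 tau = "numeric", connectivity = "integer"))

# ---------------------------------------------------------------------- show

setMethod("show", "BScan", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BScan %d x %d  patient=%s slice=%s  range [%.3f, %.3f]\n",
              d[1], d[2], object@patientId, object@sliceId,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "MaskImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("MaskImage %d x %d  foreground %d px (%.2f%%)\n", d[1], d[2],
              sum(object@pixels), 100 * mean(object@pixels)))
})

setMethod("show", "PhantomSample", function(object) {
  cat("PhantomSample\n  "); show(object@image)
  cat("  "); show(object@mask)
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit train=%d val=%d test=%d (%s)\n",
              length(object@train), length(object@val), length(object@test),
              if (object@grouped) "grouped by patient" else "by image"))
})

setMethod("show", "HRFModel", function(object) {
  cat(sprintf("HRFModel mode=%s  U channels [%s]  Kite channels [%s]  %d parameters\n",
              object@config@mode,
              paste(object@config@uChannels, collapse = ", "),
              paste(object@config@kiteChannels, collapse = ", "),
              countParameters(object)))
})

setMethod("show", "TrainHistory", function(object) {
  cat(sprintf("TrainHistory: %d epochs (best %d); final lr %.3g\n",
              object@stoppedEpoch, object@bestEpoch,
              tail(object@records$lr, 1)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d images (tau=%.2f, %d-connectivity)\n",
              object@nImages, object@tau, object@connectivity))
  cat(sprintf("  pixel : SE %.4f  P %.4f  DSC %.4f\n",
              object@pixel["se"], object@pixel["p"], object@pixel["dsc"]))
  cat(sprintf("  lesion: SE %.4f  P %.4f  DSC %.4f\n",
              object@lesion["se"], object@lesion["p"], object@lesion["dsc"]))
})

# ----------------------------------------------------------------- accessors

#' @rdname accessors
#' @param x an HRFseg object.
#' @return \code{scanArray} and \code{maskArray} return the pixel matrix;
#'   other accessors return the corresponding slot.
#' @export
scanArray <- function(x) {
  if (is(x, "PhantomSample")) x@image@pixels else x@pixels
}

#' @rdname accessors
#' @export
maskArray <- function(x) {
  if (is(x, "PhantomSample")) x@mask@pixels else x@pixels
}

#' Accessors for HRFseg containers
#' @rdname accessors
#' @export
patientId <- function(x) {
  if (is(x, "PhantomSample")) x@image@patientId else x@patientId
}

#' @rdname accessors
#' @export
sliceId <- function(x) {
  if (is(x, "PhantomSample")) x@image@sliceId else x@sliceId
}

#' @rdname accessors
#' @export
historyRecords <- function(x) x@records

#' @rdname accessors
#' @export
modelWeights <- function(x) x@weights

#' @rdname accessors
#' @export
modelConfig <- function(x) x@config

#' @rdname accessors
#' @export
pixelSummary <- function(x) x@pixel

#' @rdname accessors
#' @export
lesionSummary <- function(x) x@lesion

#' @rdname accessors
#' @export
perImageMetrics <- function(x) x@perImage

#' @rdname accessors
#' @export
splitIds <- function(x) list(train = x@train, val = x@val, test = x@test)

#' @rdname accessors
#' @export
confusionVector <- function(x) c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn)
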