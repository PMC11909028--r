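#' @include AllClasses.R
NULL

.lossClamp <- 1e-7

.checkProbsTarget <- function(probs, target) {
  p <- .asMatrix(if (is.array(probs)) probs else as.matrix(probs))
  t <- if (is(target, "MaskImage")) target@pixels else target
  if (!identical(dim(p), dim(t)))
    stop("probs and target shapes differ", call. = FALSE)
  .assertBinary(t, "target")
  list(p = .clamp(p, .lossClamp, 1 - .lossClamp), t = t)
}

#' Focal loss
#'
#' Mean over pixels of \code{-w * (1 - p_t)^gamma * log(p_t)}, where
#' \code{p_t} is the predicted probability of the pixel's true class and
#' \code{w} is \code{alpha} on foreground pixels and \code{1 - alpha} on
#' background pixels.  The focusing exponent gamma suppresses the
#' contribution of easy pixels, countering the extreme
#' foreground/background imbalance of punctate lesions.  Probabilities
#' are clamped to [1e-7, 1 - 1e-7].
#'
#' @param probs predicted probability matrix (or (H, W, 1) array).
#' @param target binary mask (matrix or \linkS4class{MaskImage}).
#' @param config a \linkS4class{LossConfig}.
#' @return Nonnegative scalar.
#' @export
focalLoss <- function(probs, target, config = LossConfig()) {
  validObject(config)
  z <- .checkProbsTarget(probs, target)
  pt <- ifelse(z$t == 1, z$p, 1 - z$p)
  w <- ifelse(z$t == 1, config@alpha, 1 - config@alpha)
  mean(-w * (1 - pt)^config@gamma * log(pt))
}

#' Soft dice loss
#'
#' \code{1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)}.  On binary
#' inputs with eps -> 0 this equals \code{1 - 2TP / (2TP + FP + FN)}, one
#' minus the dice similarity coefficient.
#'
#' @inheritParams focalLoss
#' @return Scalar in [0, 1].
#' @export
diceLoss <- function(probs, target, config = LossConfig()) {
  validObject(config)
  z <- .checkProbsTarget(probs, target)
  eps <- config@diceSmooth
  1 - (2 * sum(z$p * z$t) + eps) / (sum(z$p) + sum(z$t) + eps)
}

#' Compound dice + focal loss
#'
#' \code{w_dice * diceLoss + w_focal * focalLoss} with default weights
#' (0.5, 0.5); a convex combination of the two objectives, computed per
#' image.
#'
#' @inheritParams focalLoss
#' @return Scalar.
#' @export
combinedLoss <- function(probs, target, config = LossConfig()) {
  w <- config@weights
  w[1] * diceLoss(probs, target, config) +
    w[2] * focalLoss(probs, target, config)
}

# Gradient of the combined loss with respect to the (clamped) probability
# map; pixels at the clamp boundary get zero gradient, mirroring the
# clamping in the loss value.
.combinedLossGrad <- function(probs, target, config) {
  z <- .checkProbsTarget(probs, target)
  p <- z$p; t <- z$t
  n <- length(p)
  # focal term
  pt <- ifelse(t == 1, p, 1 - p)
  w <- ifelse(t == 1, config@alpha, 1 - config@alpha)
  g <- config@gamma
  dpt <- if (g == 0) -w / pt
         else w * (g * (1 - pt)^(g - 1) * log(pt) - (1 - pt)^g / pt)
  gFocal <- ifelse(t == 1, dpt, -dpt) / n
  # dice term
  eps <- config@diceSmooth
  num <- 2 * sum(p * t) + eps
  den <- sum(p) + sum(t) + eps
  gDice <- -(2 * t * den - num) / den^2
  g <- config@weights[1] * gDice + config@weights[2] * gFocal
  g[probs <= .lossClamp | probs >= 1 - .lossClamp] <- 0
  matrix(g, nrow(p), ncol(p))
}
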