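#' @include AllClasses.R
NULL

.maskMatrix <- function(x, what = "mask") {
  m <- if (is(x, "MaskImage")) x@pixels else x
  .assertBinary(m, what)
  m
}

#' Connected components of a binary mask
#'
#' Partitions the foreground into maximal connected sets under 4- or
#' 8-connectivity (8 by default: punctate blobs with anti-aliased corners
#' fragment under 4-connectivity).  Components are labelled
#' deterministically in column-major scan order of their first pixel.
#'
#' @param mask binary matrix or \linkS4class{MaskImage}.
#' @param connectivity 4 or 8.
#' @return List of components, each a list with \code{id}, \code{pixels}
#'   (n x 2 matrix of row/col coordinates) and \code{size}.
#' @export
connectedComponents <- function(mask, connectivity = 8L) {
  m <- .maskMatrix(mask)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  lab <- cpp_label_components(matrix(as.integer(m), nrow(m)), connectivity)
  n <- max(lab)
  if (n == 0L) return(list())
  idx <- which(lab > 0)
  co <- arrayInd(idx, dim(lab))
  bylab <- split(seq_along(idx), lab[idx])
  lapply(seq_len(n), function(i) {
    px <- co[bylab[[as.character(i)]], , drop = FALSE]
    list(id = i, pixels = px, size = nrow(px))
  })
}

# se/p/dsc from counts with the zero-denominator conventions: a vanishing
# denominator scores 0 when the other mask is nonempty, and all three
# metrics are 1 when prediction and truth are both empty.
.sepdFromCounts <- function(tp, fp, fn) {
  if (tp + fp + fn == 0) return(c(se = 1, p = 1, dsc = 1))
  c(se = if (tp + fn > 0) tp / (tp + fn) else 0,
    p = if (tp + fp > 0) tp / (tp + fp) else 0,
    dsc = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
}

#' Per-pixel segmentation metrics
#'
#' Sensitivity \code{TP/(TP+FN)}, precision \code{TP/(TP+FP)} and dice
#' \code{2TP/(2TP+FP+FN)} between a predicted and a reference binary
#' mask.  Conventions: a vanishing denominator scores 0 while the other
#' mask is nonempty; all three are 1 when both masks are empty.
#'
#' @param pred,gt binary masks of equal shape.
#' @return Named vector c(se, p, dsc).
#' @export
pixelMetrics <- function(pred, gt) {
  p <- .maskMatrix(pred, "pred"); g <- .maskMatrix(gt, "gt")
  if (!identical(dim(p), dim(g))) stop("shape mismatch", call. = FALSE)
  tp <- sum(p == 1 & g == 1)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  .sepdFromCounts(tp, fp, fn)
}

#' Lesion-level matching under the coverage rule
#'
#' Each ground-truth component g is detected (lesion-TP) when predicted
#' foreground covers at least \code{tau} of its pixels (default 0.6),
#' otherwise it counts as lesion-FN.  A predicted component counts as
#' lesion-FP iff it contributes no pixel to any detected ground-truth
#' component.  Lesion-level se/p/dsc follow from these counts by the same
#' three formulas as the pixel tier.
#'
#' @param pred,gt binary masks of equal shape.
#' @param tau coverage threshold in (0, 1].
#' @param connectivity 4 or 8.
#' @return list(counts = \linkS4class{ConfusionCounts} (tn = 0 sentinel),
#'   coverage = per-ground-truth-component coverage fractions,
#'   metrics = c(se, p, dsc)).
#' @export
lesionMatch <- function(pred, gt, tau = 0.6, connectivity = 8L) {
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]", call. = FALSE)
  p <- .maskMatrix(pred, "pred"); g <- .maskMatrix(gt, "gt")
  if (!identical(dim(p), dim(g))) stop("shape mismatch", call. = FALSE)
  gtComp <- connectedComponents(g, connectivity)
  prComp <- connectedComponents(p, connectivity)
  coverage <- vapply(gtComp, function(cc) sum(p[cc$pixels]) / cc$size, 0)
  tpFlag <- coverage >= tau
  tp <- sum(tpFlag); fn <- length(gtComp) - tp
  # detected ground-truth footprint, for the FP rule
  det <- matrix(0, nrow(g), ncol(g))
  for (i in which(tpFlag)) det[gtComp[[i]]$pixels] <- 1
  fp <- sum(vapply(prComp, function(cc) sum(det[cc$pixels]) == 0, TRUE))
  list(counts = ConfusionCounts(tp = tp, fp = fp, fn = fn, tn = 0),
       coverage = coverage, metrics = .sepdFromCounts(tp, fp, fn))
}

#' Two-tier evaluation over a dataset
#'
#' Computes per-image pixel and lesion metrics, then their unweighted
#' (macro) means.  Images with empty ground truth and empty prediction
#' score (1, 1, 1) in both tiers.
#'
#' @param preds,gts aligned lists of binary masks.
#' @param tau,connectivity lesion-matching parameters.
#' @return A \linkS4class{MetricsReport}.
#' @export
evaluateDataset <- function(preds, gts, tau = 0.6, connectivity = 8L) {
  if (length(preds) != length(gts))
    stop("preds and gts must have equal length", call. = FALSE)
  if (length(preds) == 0L) stop("nothing to evaluate", call. = FALSE)
  rows <- lapply(seq_along(preds), function(i) {
    px <- pixelMetrics(preds[[i]], gts[[i]])
    ls <- lesionMatch(preds[[i]], gts[[i]], tau, connectivity)$metrics
    data.frame(image = i, pixel_se = px["se"], pixel_p = px["p"],
               pixel_dsc = px["dsc"], lesion_se = ls["se"],
               lesion_p = ls["p"], lesion_dsc = ls["dsc"],
               row.names = NULL)
  })
  per <- do.call(rbind, rows)
  new("MetricsReport",
      pixel = c(se = mean(per$pixel_se), p = mean(per$pixel_p),
                dsc = mean(per$pixel_dsc)),
      lesion = c(se = mean(per$lesion_se), p = mean(per$lesion_p),
                 dsc = mean(per$lesion_dsc)),
      perImage = per, nImages = length(preds),
      tau = tau, connectivity = as.integer(connectivity))
}
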