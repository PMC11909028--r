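#' @include model.R losses.R metrics.R preprocess.R
NULL

#' Split sample ids into train/validation/test at 8:1:1
#'
#' Ids are shuffled with \code{seed}; \code{floor(0.8 n)} go to training
#' and the remainder is divided between validation and test with
#' validation taking the extra item when the remainder is odd (for
#' n = 173 this yields the canonical 138/18/17).  With
#' \code{groupByPatient = TRUE} the allocation operates on patient blocks
#' so all of a patient's slices travel together.
#'
#' @param ids character vector of sample ids ("<patient>_<slice>" when
#'   grouping).
#' @param seed shuffling seed.
#' @param groupByPatient keep each patient within one subset.
#' @param patientOf optional function mapping an id to its patient id;
#'   defaults to stripping the last "_<slice>" component.
#' @return A \linkS4class{DatasetSplit}.
#' @export
splitDataset <- function(ids, seed = 1L, groupByPatient = FALSE,
                         patientOf = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  alloc <- function(units) {
    n <- length(units)
    if (n < 3L) stop("need at least 3 units to split", call. = FALSE)
    units <- .withSeed(seed, sample(units))
    nTrain <- floor(0.8 * n)
    rest <- n - nTrain
    nVal <- ceiling(rest / 2)
    list(train = units[seq_len(nTrain)],
         val = units[nTrain + seq_len(nVal)],
         test = units[(nTrain + nVal + 1L):n])
  }
  if (!groupByPatient) {
    a <- alloc(ids)
    return(new("DatasetSplit", train = a$train, val = a$val, test = a$test,
               grouped = FALSE, seed = as.integer(seed)))
  }
  if (is.null(patientOf))
    patientOf <- function(id) sub("_[^_]*$", "", id)
  pat <- vapply(ids, patientOf, "")
  a <- alloc(unique(pat))
  new("DatasetSplit",
      train = ids[pat %in% a$train], val = ids[pat %in% a$val],
      test = ids[pat %in% a$test], grouped = TRUE, seed = as.integer(seed))
}

# One step of the plateau learning-rate schedule.  `state` carries the
# best monitored value, the epochs waited since improvement, and the
# current lr; each plateau of `patience` epochs multiplies lr by `factor`.
.plateauStep <- function(state, value, higherBetter, patience, factor) {
  improved <- if (is.null(state$best)) TRUE
              else if (higherBetter) value > state$best + 1e-12
              else value < state$best - 1e-12
  if (improved) {
    state$best <- value
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= patience) {
      state$lr <- state$lr * factor
      state$wait <- 0L
    }
  }
  state$improved <- improved
  state
}

# Adam update in place on a weight list.
.adamStep <- function(w, grads, st, lr, b1, b2, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(w)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- if (is.null(st$m[[nm]])) g * 0 else st$m[[nm]]
    v <- if (is.null(st$v[[nm]])) g * 0 else st$v[[nm]]
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    st$m[[nm]] <- m; st$v[[nm]] <- v
    w[[nm]] <- w[[nm]] - lr * (m / c1) / (sqrt(v / c2) + eps)
  }
  w
}

# Forward + loss + full backward for one sample; returns loss and the
# parameter gradients accumulated on the tape.
.trainStep <- function(weights, config, im, mk, lossConfig) {
  tp <- .tapeNew(weights)
  out <- .buildForward(tp, config, .opInput(tp, .asChannel(im)))
  probs <- .asMatrix(.tpVal(tp, out$prob))
  loss <- combinedLoss(probs, mk, lossConfig)
  gProb <- .combinedLossGrad(probs, mk, lossConfig)
  .tpBackward(tp, out$prob, .asChannel(gProb))
  list(loss = loss, grads = as.list(tp$pgrad))
}

#' Fit the segmentation network
#'
#' Adam at batch size one with on-the-fly augmentation, plateau-based
#' learning-rate halving (after \code{plateauPatience} epochs without
#' improvement of the monitored quantity) and early stopping (after
#' \code{earlyStopPatience} epochs without improvement).  The weights of
#' the best monitored epoch are returned.  Fully reproducible under
#' \code{trainConfig@seed}.
#'
#' @param modelConfig a \linkS4class{ModelConfig}.
#' @param samples list of \linkS4class{PhantomSample}.
#' @param split a \linkS4class{DatasetSplit} over \code{sampleId}s.
#' @param trainConfig a \linkS4class{TrainConfig}.
#' @param lossConfig a \linkS4class{LossConfig}.
#' @param augmentPolicy an \linkS4class{AugmentPolicy}, or NULL to train
#'   without augmentation.
#' @param verbose print one line per epoch.
#' @return list(model = fitted \linkS4class{HRFModel},
#'   history = \linkS4class{TrainHistory}).
#' @export
fitModel <- function(modelConfig, samples, split,
                     trainConfig = TrainConfig(),
                     lossConfig = LossConfig(),
                     augmentPolicy = NULL, verbose = FALSE) {
  validObject(trainConfig); validObject(lossConfig)
  ids <- vapply(samples, sampleId, "")
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  byId <- stats::setNames(samples, ids)
  trainS <- byId[split@train]; valS <- byId[split@val]
  if (any(vapply(trainS, is.null, TRUE)) || any(vapply(valS, is.null, TRUE)))
    stop("split references unknown sample ids", call. = FALSE)

  model <- initModel(modelConfig, seed = trainConfig@seed)
  w <- model@weights
  adam <- new.env(parent = emptyenv()); adam$t <- 0L
  adam$m <- list(); adam$v <- list()
  higher <- trainConfig@monitor == "val_dsc"
  lrState <- list(best = NULL, wait = 0L, lr = trainConfig@lr)
  esBest <- NULL; esWait <- 0L
  bestW <- w; bestEpoch <- 1L
  hist <- NULL

  .withSeed(trainConfig@seed, {
    for (epoch in seq_len(trainConfig@epochs)) {
      lrEpoch <- lrState$lr
      ord <- sample(seq_along(trainS))
      losses <- numeric(0)
      for (i in ord) {
        s <- trainS[[i]]
        im <- scanArray(s); mk <- maskArray(s)
        if (!is.null(augmentPolicy)) {
          a <- .applyAugment(im, mk,
                 .augmentDraws(augmentPolicy, floor(runif(1) * 2^31)))
          im <- a$image; mk <- a$mask
        }
        st <- .trainStep(w, modelConfig, im, mk, lossConfig)
        if (!is.finite(st$loss))
          stop("training diverged at epoch ", epoch,
               ": non-finite loss", call. = FALSE)
        losses <- c(losses, st$loss)
        w <- .adamStep(w, st$grads, adam, lrEpoch,
                       trainConfig@beta1, trainConfig@beta2)
      }
      valLoss <- valDsc <- numeric(0)
      for (s in valS) {
        pr <- forwardModel(new("HRFModel", config = modelConfig, weights = w,
                               seed = trainConfig@seed), scanArray(s))
        valLoss <- c(valLoss, combinedLoss(pr, maskArray(s), lossConfig))
        valDsc <- c(valDsc,
                    pixelMetrics(matrix(as.numeric(pr >= 0.5), nrow(pr)),
                                 maskArray(s))["dsc"])
      }
      rec <- data.frame(epoch = epoch, train_loss = mean(losses),
                        val_loss = mean(valLoss), val_dsc = mean(valDsc),
                        lr = lrEpoch)
      hist <- rbind(hist, rec)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  dsc %.4f  lr %.2g",
                        epoch, rec$train_loss, rec$val_loss, rec$val_dsc,
                        lrEpoch))
      mon <- switch(trainConfig@monitor, train_loss = rec$train_loss,
                    val_loss = rec$val_loss, val_dsc = rec$val_dsc)
      lrState <- .plateauStep(lrState, mon, higher,
                              trainConfig@plateauPatience,
                              trainConfig@lrFactor)
      impES <- if (is.null(esBest)) TRUE
               else if (higher) mon > esBest + 1e-12 else mon < esBest - 1e-12
      if (impES) {
        esBest <- mon; esWait <- 0L
        bestW <- w; bestEpoch <- epoch
      } else {
        esWait <- esWait + 1L
        if (esWait >= trainConfig@earlyStopPatience) break
      }
    }
  })

  list(model = new("HRFModel", config = modelConfig, weights = bestW,
                   seed = trainConfig@seed),
       history = new("TrainHistory", records = hist,
                     stoppedEpoch = as.integer(max(hist$epoch)),
                     bestEpoch = as.integer(bestEpoch)))
}

#' Predict binary HRF masks
#'
#' Forward pass followed by thresholding of the probability map.
#'
#' @param model a fitted \linkS4class{HRFModel}.
#' @param images list of \linkS4class{BScan}s or matrices (preprocessed to
#'   the model's working size).
#' @param threshold binarisation threshold in (0, 1), default 0.5.
#' @return List of \linkS4class{MaskImage}.
#' @export
predictMasks <- function(model, images, threshold = 0.5) {
  if (!is.list(images)) images <- list(images)
  lapply(images, function(im) {
    pr <- forwardModel(model, im)
    MaskImage(matrix(as.numeric(pr >= threshold), nrow(pr), ncol(pr)))
  })
}
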