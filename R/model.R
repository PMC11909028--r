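#' @include nn.R AllClasses.R
NULL

# Weight-name inventory per mode.  The dual model is, by construction, the
# disjoint union of the u_only submodule, the kite_only submodule and the
# cross-attention blocks: its output logit is the sum of the two per-branch
# 1x1 head convolutions.
.initWeightsFor <- function(config, seed) {
  cu <- config@uChannels; ck <- config@kiteChannels
  norm <- config@norm; mode <- config@mode
  # Prior-probability head-bias initialisation: start the sigmoid output
  # near the foreground prevalence (~1%) so the first epochs are not spent
  # un-learning a 50% background estimate; with two heads summed (dual
  # mode) each head carries half the prior logit.
  nHeads <- if (mode == "dual") 2 else 1
  priorBias <- log(0.01 / 0.99) / nHeads
  .withSeed(seed, {
    w <- list()
    if (mode %in% c("dual", "u_only")) {
      w <- .initBlock(w, "ue1", 1L, cu[1], norm)
      w <- .initBlock(w, "ue2", cu[1], cu[2], norm)
      w <- .initBlock(w, "ue3", cu[2], cu[3], norm)
      w <- .initBlock(w, "ud2", cu[3] + cu[2], cu[2], norm)
      w <- .initBlock(w, "ud1", cu[2] + cu[1], cu[1], norm)
      w[["headu_w"]] <- .initConv(1L, 1L, cu[1], 1L)
      w[["headu_b"]] <- priorBias
    }
    if (mode %in% c("dual", "kite_only")) {
      w <- .initBlock(w, "ke1", 1L, ck[1], norm)
      w <- .initBlock(w, "ke2", ck[1], ck[2], norm)
      w <- .initBlock(w, "kd1", ck[2] + ck[1], ck[1], norm)
      w <- .initBlock(w, "kd0", ck[1], ck[1], norm)
      w[["headk_w"]] <- .initConv(1L, 1L, ck[1], 1L)
      w[["headk_b"]] <- priorBias
    }
    if (mode == "dual") {
      for (i in seq_len(nrow(config@cabPairings))) {
        ch <- ck[config@cabPairings[i, 1]]
        w <- .initCABSide(w, sprintf("cab%d_u", i), ch)
        w <- .initCABSide(w, sprintf("cab%d_k", i), ch)
      }
    }
    w
  })
}

#' Initialise a segmentation model
#'
#' Weights are Kaiming-uniform (fan-in) with zero biases, drawn from a
#' private RNG stream seeded by \code{seed}.
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param seed initialisation seed.
#' @return An \linkS4class{HRFModel}.
#' @export
initModel <- function(config = ModelConfig(), seed = 1L) {
  validObject(config)
  new("HRFModel", config = config,
      weights = .initWeightsFor(config, seed), seed = as.integer(seed))
}

# Forward pass on a tape.  Returns the node ids of the logit and
# probability maps.  `x` is the input node id of an (H, W, 1) array with
# H, W divisible by 4.
.buildForward <- function(tp, config, x) {
  d <- dim(.tpVal(tp, x)); H <- d[1]; W <- d[2]
  norm <- config@norm; mode <- config@mode
  logit <- NULL
  e1 <- e2 <- e3 <- ki1 <- ki2 <- NULL
  if (mode %in% c("dual", "u_only")) {
    e1 <- .fwdBlock(tp, x, "ue1", norm)
    e2 <- .fwdBlock(tp, .opPool(tp, e1), "ue2", norm)
  }
  if (mode %in% c("dual", "kite_only")) {
    ki1 <- .opResize(tp, .fwdBlock(tp, x, "ke1", norm), 2L * H, 2L * W)
  }
  if (mode == "dual") {  # CAB at pairing (kite 1, U 2): resample factor 4
    aU <- .fwdCABSide(tp, e2, ki1, "cab1_u")
    aK <- .fwdCABSide(tp, ki1, e2, "cab1_k")
    e2 <- .opAttnGate(tp, e2, aU)
    ki1 <- .opAttnGate(tp, ki1, aK)
  }
  if (mode %in% c("dual", "u_only"))
    e3 <- .fwdBlock(tp, .opPool(tp, e2), "ue3", norm)
  if (mode %in% c("dual", "kite_only"))
    ki2 <- .opResize(tp, .fwdBlock(tp, ki1, "ke2", norm), 4L * H, 4L * W)
  if (mode == "dual") {  # CAB at pairing (kite 2, U 3): resample factor 16
    aU <- .fwdCABSide(tp, e3, ki2, "cab2_u")
    aK <- .fwdCABSide(tp, ki2, e3, "cab2_k")
    e3 <- .opAttnGate(tp, e3, aU)
    ki2 <- .opAttnGate(tp, ki2, aK)
  }
  if (mode %in% c("dual", "u_only")) {
    d2 <- .fwdBlock(tp, .opConcat(tp, .opResize(tp, e3, H %/% 2L, W %/% 2L), e2),
                    "ud2", norm)
    d1 <- .fwdBlock(tp, .opConcat(tp, .opResize(tp, d2, H, W), e1), "ud1", norm)
    logit <- .opConv(tp, d1, "headu")
  }
  if (mode %in% c("dual", "kite_only")) {
    kd1 <- .fwdBlock(tp, .opConcat(tp, .opPool(tp, ki2), ki1), "kd1", norm)
    kd0 <- .fwdBlock(tp, .opPool(tp, kd1), "kd0", norm)
    lk <- .opConv(tp, kd0, "headk")
    logit <- if (is.null(logit)) lk else .opAdd2(tp, logit, lk)
  }
  list(logit = logit, prob = .opSigmoid(tp, logit))
}

#' Forward pass: B-scan to HRF probability map
#'
#' @param model an \linkS4class{HRFModel}.
#' @param image a \linkS4class{BScan} or numeric matrix in [0, 1].  Height
#'   and width must be divisible by 4 (two poolings); with
#'   \code{inputPolicy = "resize"} other sizes are resized to the nearest
#'   working size and the probability map resized back, with
#'   \code{"reject"} they raise an error.
#' @return Probability matrix of the input size, values strictly in (0, 1).
#' @export
forwardModel <- function(model, image) {
  m <- if (is(image, "BScan")) image@pixels else image
  H <- nrow(m); W <- ncol(m)
  if (H %% 4L != 0L || W %% 4L != 0L) {
    if (model@config@inputPolicy == "reject")
      stop("input size must be divisible by 4; got ", H, " x ", W,
           " (set inputPolicy = \"resize\" to resample)", call. = FALSE)
    H4 <- max(32L, 4L * (H %/% 4L)); W4 <- max(32L, 4L * (W %/% 4L))
    mr <- .asMatrix(cpp_resize_bilinear(.asChannel(m), H4, W4))
    pr <- forwardModel(model, mr)
    return(.asMatrix(cpp_resize_bilinear(.asChannel(pr), H, W)))
  }
  tp <- .tapeNew(model@weights)
  out <- .buildForward(tp, model@config, .opInput(tp, .asChannel(m)))
  .asMatrix(.tpVal(tp, out$prob))
}

#' Cross-attention block
#'
#' Fuses a U-branch feature map \code{fU} (C channels, coarse grid) with a
#' Kite-branch feature map \code{fKi} (C channels, fine grid).  Each side
#' resamples the other branch bilinearly to its own grid, projects both
#' through 1x1 convolutions that halve the channel count, adds them,
#' applies ReLU, projects to a single channel, and squashes with a sigmoid
#' to obtain an attention map in (0, 1); the output is the residual gating
#' \code{f + alpha * f}.
#'
#' @param fU,fKi (H, W, C) arrays with equal C; spatial sizes must be
#'   related by an integral factor.
#' @param weights weight list as produced by \code{\link{cabWeights}};
#'   defaults to a Kaiming draw with seed 1.
#' @return list(fU, fKi, alphaU, alphaKi): the two gated outputs (same
#'   shapes as the inputs) and the two attention maps.
#' @export
crossAttentionBlock <- function(fU, fKi, weights = NULL) {
  dU <- dim(fU); dK <- dim(fKi)
  if (length(dU) != 3L || length(dK) != 3L)
    stop("feature maps must be (H, W, C) arrays", call. = FALSE)
  if (dU[3] != dK[3])
    stop("cross-attention requires equal channel counts; got ",
         dU[3], " and ", dK[3], call. = FALSE)
  rh <- dK[1] / dU[1]; rw <- dK[2] / dU[2]
  if (abs(rh - rw) > 1e-9 || abs(rh - round(rh)) > 1e-9)
    stop("spatial sizes must be related by one integral resample factor; ",
         "got ", rh, " x ", rw, call. = FALSE)
  if (is.null(weights)) weights <- cabWeights(dU[3])
  tp <- .tapeNew(weights)
  u <- .opInput(tp, fU); k <- .opInput(tp, fKi)
  aU <- .fwdCABSide(tp, u, k, "cab_u")
  aK <- .fwdCABSide(tp, k, u, "cab_k")
  outU <- .opAttnGate(tp, u, aU)
  outK <- .opAttnGate(tp, k, aK)
  list(fU = .tpVal(tp, outU), fKi = .tpVal(tp, outK),
       alphaU = .asMatrix(.tpVal(tp, aU)), alphaKi = .asMatrix(.tpVal(tp, aK)))
}

#' Construct cross-attention weights
#'
#' @param channels shared channel count of the two inputs (even).
#' @param init "kaiming" or "zeros"; zero weights give identically 0
#'   logits, hence attention 0.5 everywhere and output 1.5 x input.
#' @param logitBias additive bias on the final 1x1 projection; a large
#'   negative value drives the attention map to 0 and the block to the
#'   identity.
#' @param seed RNG seed for the Kaiming draw.
#' @return Named weight list for \code{\link{crossAttentionBlock}}.
#' @export
cabWeights <- function(channels, init = c("kaiming", "zeros"),
                       logitBias = 0, seed = 1L) {
  init <- match.arg(init)
  w <- .withSeed(seed, {
    w <- list()
    w <- .initCABSide(w, "cab_u", channels)
    .initCABSide(w, "cab_k", channels)
  })
  if (init == "zeros") for (nm in names(w)) w[[nm]] <- w[[nm]] * 0
  w[["cab_u_pf_b"]] <- w[["cab_u_pf_b"]] + logitBias
  w[["cab_k_pf_b"]] <- w[["cab_k_pf_b"]] + logitBias
  w
}

#' Receptive-field growth and shrinkage across encoder levels
#'
#' With 2x2/stride-2 pooling, a feature whose receptive field is kappa at
#' level 1 sees \code{2^(2(i-1)) * kappa} pixels at level i; replacing the
#' pooling with factor-2 bilinear upsampling (the over-complete encoder)
#' shrinks it to \code{(1/2)^(2(i-1)) * kappa}.
#'
#' @param kappa base receptive-field side in pixels (> 0).
#' @param layerIndex encoder level i >= 1.
#' @return Receptive-field side in pixels.
#' @export
receptiveFieldU <- function(kappa, layerIndex) {
  stopifnot(kappa > 0, layerIndex >= 1)
  2^(2 * (layerIndex - 1)) * kappa
}

#' @rdname receptiveFieldU
#' @export
receptiveFieldKite <- function(kappa, layerIndex) {
  stopifnot(kappa > 0, layerIndex >= 1)
  (1 / 2)^(2 * (layerIndex - 1)) * kappa
}

#' Trainable-parameter count
#'
#' @param x an \linkS4class{HRFModel} or \linkS4class{ModelConfig}.
#' @return Total number of trainable scalars.
#' @export
countParameters <- function(x) {
  w <- if (is(x, "HRFModel")) x@weights
       else .initWeightsFor(x, 1L)
  sum(vapply(w, length, 0L))
}

#' Parameter count of a reference four-level U-Net
#'
#' Builds, with the same block constructors used by the dual model, a
#' standard four-level U-Net with base width \code{base} (channels
#' base, 2*base, 4*base, 8*base) and returns its trainable-parameter
#' count.  Serves as the comparison point for the parameter-economy claim
#' of the dual design.
#'
#' @param base channels of the first level (default 64).
#' @param norm include normalisation parameters (matching the dual
#'   model's default).
#' @return Parameter count.
#' @export
referenceUNetParameterCount <- function(base = 64L, norm = TRUE) {
  ch <- base * c(1L, 2L, 4L, 8L)
  w <- .withSeed(1L, {
    w <- list()
    w <- .initBlock(w, "e1", 1L, ch[1], norm)
    w <- .initBlock(w, "e2", ch[1], ch[2], norm)
    w <- .initBlock(w, "e3", ch[2], ch[3], norm)
    w <- .initBlock(w, "e4", ch[3], ch[4], norm)
    w <- .initBlock(w, "d3", ch[4] + ch[3], ch[3], norm)
    w <- .initBlock(w, "d2", ch[3] + ch[2], ch[2], norm)
    w <- .initBlock(w, "d1", ch[2] + ch[1], ch[1], norm)
    w[["head_w"]] <- .initConv(1L, 1L, ch[1], 1L)
    w[["head_b"]] <- numeric(1L)
    w
  })
  sum(vapply(w, length, 0L))
}
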