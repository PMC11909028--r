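# Minimal reverse-mode autodiff over (H, W, C) activation arrays.
#
# A tape is an environment holding a list of nodes; each node stores its
# value and a backward closure mapping the node's output gradient to
# gradients for its parents (by node id).  Parameter gradients are
# accumulated by name into tape$pgrad as a side effect, which keeps the
# graph small (parameters are captured, not nodes).

.tapeNew <- function(weights) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$w <- weights
  tp$pgrad <- new.env(parent = emptyenv())
  tp
}

.tpAdd <- function(tp, value, parents = integer(0), backfn = NULL) {
  id <- length(tp$nodes) + 1L
  tp$nodes[[id]] <- list(value = value, parents = parents, backfn = backfn)
  id
}

.tpVal <- function(tp, id) {
  force(id)  # ids may arrive as promises that append nodes when forced
  tp$nodes[[id]]$value
}

.accumPar <- function(tp, name, g) {
  cur <- tp$pgrad[[name]]
  tp$pgrad[[name]] <- if (is.null(cur)) g else cur + g
}

# Backward sweep from node `seedId` with output gradient `seedGrad`;
# afterwards tape$pgrad holds d(loss)/d(parameter) for every parameter
# touched by the forward pass.
.tpBackward <- function(tp, seedId, seedGrad) {
  n <- length(tp$nodes)
  grads <- vector("list", n)
  grads[[seedId]] <- seedGrad
  for (id in seq(n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tp$nodes[[id]]
    if (is.null(nd$backfn)) next
    pg <- nd$backfn(g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[k]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
    grads[[id]] <- NULL  # free
  }
  invisible(NULL)
}

# ------------------------------------------------------------------ tape ops

.opInput <- function(tp, value) .tpAdd(tp, value)

.opConv <- function(tp, x, wname) {
  w <- tp$w[[paste0(wname, "_w")]]; b <- tp$w[[paste0(wname, "_b")]]
  xv <- .tpVal(tp, x)
  out <- cpp_conv2d_fwd(xv, w, b)
  .tpAdd(tp, out, parents = x, backfn = function(g) {
    bw <- cpp_conv2d_bwd(xv, w, g)
    .accumPar(tp, paste0(wname, "_w"), bw$gw)
    .accumPar(tp, paste0(wname, "_b"), bw$gb)
    list(bw$gx)
  })
}

.opRelu <- function(tp, x) {
  out <- cpp_relu_fwd(.tpVal(tp, x))
  .tpAdd(tp, out, parents = x, backfn = function(g) list(cpp_relu_bwd(out, g)))
}

.opSigmoid <- function(tp, x) {
  s <- 1 / (1 + exp(-.tpVal(tp, x)))
  .tpAdd(tp, s, parents = x, backfn = function(g) list(g * s * (1 - s)))
}

.opAdd2 <- function(tp, a, b) {
  .tpAdd(tp, .tpVal(tp, a) + .tpVal(tp, b), parents = c(a, b),
         backfn = function(g) list(g, g))
}

# out = x * (1 + a), a broadcast over channels (a has 1 channel): the
# residual attention gating out = f + alpha (.) f.
.opAttnGate <- function(tp, x, a) {
  xv <- .tpVal(tp, x); av <- .tpVal(tp, a)
  .tpAdd(tp, cpp_attngate_fwd(xv, av), parents = c(x, a), backfn = function(g) {
    bw <- cpp_attngate_bwd(g, xv, av)
    list(bw$gx, bw$ga)
  })
}

.opPool <- function(tp, x) {
  xv <- .tpVal(tp, x)
  d <- dim(xv)
  r <- cpp_maxpool2_fwd(xv)
  .tpAdd(tp, r$out, parents = x, backfn = function(g)
    list(cpp_maxpool2_bwd(r$idx, g, d[1], d[2], d[3])))
}

.opResize <- function(tp, x, oh, ow) {
  xv <- .tpVal(tp, x)
  d <- dim(xv)
  if (d[1] == oh && d[2] == ow) return(x)
  .tpAdd(tp, cpp_resize_bilinear(xv, oh, ow), parents = x,
         backfn = function(g) list(cpp_resize_bilinear_bwd(g, d[1], d[2])))
}

.opConcat <- function(tp, a, b) {
  av <- .tpVal(tp, a); bv <- .tpVal(tp, b)
  da <- dim(av); db <- dim(bv)
  out <- array(c(av, bv), c(da[1], da[2], da[3] + db[3]))
  .tpAdd(tp, out, parents = c(a, b), backfn = function(g) {
    list(array(g[, , seq_len(da[3]), drop = FALSE], da),
         array(g[, , da[3] + seq_len(db[3]), drop = FALSE], db))
  })
}

# Per-channel (instance) normalisation with learnable scale/shift; used
# inside conv blocks when config@norm is TRUE.  eps keeps the variance
# denominator away from zero.
.opNorm <- function(tp, x, wname, eps = 1e-5) {
  gamma <- tp$w[[paste0(wname, "_g")]]; beta <- tp$w[[paste0(wname, "_s")]]
  r <- cpp_instnorm_fwd(.tpVal(tp, x), gamma, beta, eps)
  .tpAdd(tp, r$out, parents = x, backfn = function(g) {
    bw <- cpp_instnorm_bwd(g, r$xhat, r$isd, gamma)
    .accumPar(tp, paste0(wname, "_g"), bw$ggamma)
    .accumPar(tp, paste0(wname, "_s"), bw$gbeta)
    list(bw$gx)
  })
}

# ------------------------------------------------------------ initialisation

# Kaiming-uniform fan-in initialisation for a (kh, kw, cin, cout) kernel.
.initConv <- function(kh, kw, cin, cout) {
  fan <- kh * kw * cin
  bound <- sqrt(6 / fan)
  array(runif(kh * kw * cin * cout, -bound, bound), c(kh, kw, cin, cout))
}

# Parameters of one conv block: two 3x3 convolutions (+ optional norm).
.initBlock <- function(w, name, cin, cout, norm) {
  w[[paste0(name, "_c1_w")]] <- .initConv(3L, 3L, cin, cout)
  w[[paste0(name, "_c1_b")]] <- numeric(cout)
  w[[paste0(name, "_c2_w")]] <- .initConv(3L, 3L, cout, cout)
  w[[paste0(name, "_c2_b")]] <- numeric(cout)
  if (norm) {
    w[[paste0(name, "_n1_g")]] <- rep(1, cout)
    w[[paste0(name, "_n1_s")]] <- numeric(cout)
    w[[paste0(name, "_n2_g")]] <- rep(1, cout)
    w[[paste0(name, "_n2_s")]] <- numeric(cout)
  }
  w
}

# One side of a cross-attention block: two 1x1 channel-halving
# projections and the 1x1 logit projection to a single channel.
.initCABSide <- function(w, name, channels) {
  half <- channels %/% 2L
  w[[paste0(name, "_pa_w")]] <- .initConv(1L, 1L, channels, half)
  w[[paste0(name, "_pa_b")]] <- numeric(half)
  w[[paste0(name, "_pb_w")]] <- .initConv(1L, 1L, channels, half)
  w[[paste0(name, "_pb_b")]] <- numeric(half)
  w[[paste0(name, "_pf_w")]] <- .initConv(1L, 1L, half, 1L)
  w[[paste0(name, "_pf_b")]] <- numeric(1L)
  w
}

# Forward through one conv block.
.fwdBlock <- function(tp, x, name, norm) {
  x <- .opConv(tp, x, paste0(name, "_c1"))
  if (norm) x <- .opNorm(tp, x, paste0(name, "_n1"))
  x <- .opRelu(tp, x)
  x <- .opConv(tp, x, paste0(name, "_c2"))
  if (norm) x <- .opNorm(tp, x, paste0(name, "_n2"))
  .opRelu(tp, x)
}

# Attention map of one CAB side: sigmoid(1x1( relu( 1x1(own) +
# 1x1(resampled other) ) )), a single channel in (0, 1).
.fwdCABSide <- function(tp, own, other, name) {
  d <- dim(.tpVal(tp, own))
  qo <- .opConv(tp, own, paste0(name, "_pa"))
  qr <- .opConv(tp, .opResize(tp, other, d[1], d[2]), paste0(name, "_pb"))
  s <- .opRelu(tp, .opAdd2(tp, qo, qr))
  .opSigmoid(tp, .opConv(tp, s, paste0(name, "_pf")))
}
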