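# Internal helpers shared across modules.

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so generators are pure functions of
# (arguments, seed).
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Derive a bounded child seed from a base seed and one or more integer
# tags; keeps every derived seed in [1, 2^31 - 2].
.deriveSeed <- function(seed, ...) {
  tags <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (t in tags) h <- (h * 48271 + as.numeric(t) * 7919 + 1) %% 2147483647
  as.integer(h %% 2147483645) + 1L
}

.assertBinary <- function(m, what = "mask") {
  if (!all(m %in% c(0, 1)))
    stop(what, " must be strictly binary (0/1)", call. = FALSE)
  invisible(TRUE)
}

.asMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (!is.null(d) && length(d) == 3 && d[3] == 1) return(array(x, d[1:2]))
  stop("expected a 2D grid", call. = FALSE)
}

# (H, W) matrix -> (H, W, 1) array, the network's single-channel layout.
.asChannel <- function(m) array(m, c(nrow(m), ncol(m), 1L))
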