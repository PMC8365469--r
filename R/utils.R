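# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation: one master integer fans out to
# per-repeat / per-stage seeds, all < 2^31 - 1.
derive_seed <- function(master_seed, ...) {
  idx <- c(...)
  s <- as.double(master_seed) %% 2147483647
  for (i in idx) {
    s <- (s * 1009 + as.double(i) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

# Squared Euclidean distances between rows of X and rows of Y.
pairwise_sqdist <- function(X, Y) {
  xx <- rowSums(X^2)
  yy <- rowSums(Y^2)
  d2 <- outer(xx, yy, "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  d2
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}
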