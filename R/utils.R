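## Internal helpers.

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Separable Gaussian smoothing of a matrix with edge renormalization;
# sigma in cells. Used by the synthetic landscape generator.
gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  smooth1 <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      kk <- k[j - i + r + 1L]
      out[i] <- sum(kk * x[j]) / sum(kk)
    }
    out
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

# Rescale a matrix linearly onto [lo, hi]; constant input maps to lo.
rescaleTo <- function(m, lo, hi) {
  rng <- range(m)
  if (diff(rng) < 1e-12) return(matrix(lo, nrow(m), ncol(m)))
  lo + (m - rng[1]) / diff(rng) * (hi - lo)
}
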