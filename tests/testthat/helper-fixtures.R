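# Shared fixtures: all synthetic, generated in code.

# random positive reciprocal matrix on the Saaty scale
randomSaaty <- function(n, seed) {
  set.seed(seed)
  vals <- c(1/(9:2), 1:9)
  A <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    A[i, j] <- sample(vals, 1)
    A[j, i] <- 1 / A[i, j]
  }
  pairwiseMatrix(A)
}

# perfectly consistent matrix a_ij = w_i / w_j
consistentMatrix <- function(w) {
  pairwiseMatrix(outer(w, w, "/"))
}

# independent principal-eigenvector oracle by power iteration
powerIterWeights <- function(A, iters = 1000) {
  w <- rep(1, nrow(A)) / nrow(A)
  for (i in seq_len(iters)) {
    w <- as.vector(A %*% w)
    w <- w / sum(w)
  }
  w
}

# small grid helpers
gridOf <- function(v, nrow = 2, cellsize = 250, units = "") {
  rasterGrid(matrix(v, nrow = nrow), cellsize = cellsize, units = units)
}

# printed 2-decimal criterion weights (published rounding)
printedRiceWeights <- c(rainfall = 0.29, temperature = 0.03, drainage = 0.25,
                        depth = 0.11, texture = 0.16, slope = 0.06,
                        elevation = 0.06, soc = 0.04, ph = 0.02)
printedCoconutWeights <- c(elevation = 0.04, slope = 0.06, depth = 0.15,
                           texture = 0.08, drainage = 0.11, rainfall = 0.31,
                           temperature = 0.22, ph = 0.03, soc = 0.02)

# one shared small landscape for the slower tests
sharedLandscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateLandscape(landscapeConfig())
    cache
  }
})
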