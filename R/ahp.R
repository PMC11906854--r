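## AHP engine: weight derivation, consistency diagnostics, matrix I/O.

#' Construct a pairwise comparison matrix
#'
#' @param entries square numeric matrix of Saaty-scale judgments, or a matrix
#'   with only the upper triangle filled when `autoReciprocal = TRUE`.
#' @param labels criterion names; defaults to existing dimnames or C1..Cn.
#' @param autoReciprocal if TRUE the upper triangle is authoritative and the
#'   lower triangle is overwritten with exact reciprocals.
#' @return A [PairwiseMatrix-class].
#' @examples
#' m <- pairwiseMatrix(rbind(c(1, 3), c(1/3, 1)), c("rain", "slope"))
#' ahpWeights(m)
#' @export
pairwiseMatrix <- function(entries, labels = NULL, autoReciprocal = FALSE) {
  entries <- as.matrix(entries)
  if (is.null(labels))
    labels <- if (!is.null(rownames(entries))) rownames(entries)
              else paste0("C", seq_len(nrow(entries)))
  if (autoReciprocal) {
    n <- nrow(entries)
    for (i in seq_len(n)) for (j in seq_len(n))
      if (j > i) entries[j, i] <- 1 / entries[i, j] else if (j == i)
        entries[i, i] <- 1
  }
  dimnames(entries) <- list(labels, labels)
  new("PairwiseMatrix", entries = entries, labels = labels)
}

#' Derive criterion weights by column normalization
#'
#' Each column is divided by its column sum; the weight of criterion i is the
#' mean of normalized row i (equivalently its row total divided by n). This
#' is the classical approximate eigenvector of the AHP workflow.
#'
#' @param matrix a [PairwiseMatrix-class].
#' @return named numeric weights summing to 1.
#' @export
ahpWeights <- function(matrix) {
  stopifnot(is(matrix, "PairwiseMatrix"))
  A <- matrix@entries
  w <- rowMeans(sweep(A, 2, colSums(A), "/"))
  names(w) <- matrix@labels
  w
}

#' Maximum-eigenvalue estimate of a judgment matrix
#'
#' Computes the consistency vector (A w)_i / w_i and summarises it. The
#' spreadsheet AHP workflow (matrix product of A with the approximate weight
#' vector, then row-wise division) reports the *maximum* of that vector as
#' lambda_max, which is what `method = "rowmax"` returns and is the package
#' default. `"rowmean"` returns the Saaty mean estimate, and `"eigen"` the
#' exact principal eigenvalue. For a perfectly consistent matrix all three
#' equal n.
#'
#' @param matrix a [PairwiseMatrix-class].
#' @param weights weight vector from [ahpWeights()] on the same matrix
#'   (recomputed when omitted).
#' @param method one of "rowmax" (default), "rowmean", "eigen".
#' @return single numeric >= n.
#' @export
lambdaMax <- function(matrix, weights = NULL,
                      method = c("rowmax", "rowmean", "eigen")) {
  stopifnot(is(matrix, "PairwiseMatrix"))
  method <- match.arg(method)
  A <- matrix@entries
  if (method == "eigen")
    return(max(Re(eigen(A, only.values = TRUE)$values)))
  if (is.null(weights)) weights <- ahpWeights(matrix)
  if (length(weights) != nrow(A))
    stop("weights length does not match matrix order")
  cv <- as.vector(A %*% weights) / weights
  if (method == "rowmax") max(cv) else mean(cv)
}

#' Consistency index CI = (lambda_max - n) / (n - 1)
#'
#' @param lambdaMax maximum-eigenvalue estimate.
#' @param n matrix order (>= 2).
#' @return single numeric, >= 0 up to numerical noise.
#' @export
consistencyIndex <- function(lambdaMax, n) {
  if (n < 2) stop("consistency index is undefined for n < 2")
  if (lambdaMax < n - 1e-6)
    stop("lambdaMax below n: not a valid reciprocal-matrix estimate")
  (lambdaMax - n) / (n - 1)
}

#' Random consistency index (Saaty)
#'
#' Tabulated average CI of random reciprocal matrices, used as the CR
#' denominator. Defined here for orders 1 through 10.
#'
#' @param n matrix order, 1..10.
#' @return single numeric.
#' @export
randomIndex <- function(n) {
  ri <- c(0, 0, 0.58, 0.9, 1.12, 1.24, 1.32, 1.41, 1.46, 1.49)
  if (length(n) != 1L || n != round(n) || n < 1 || n > 10)
    stop("random index is tabulated for n in 1..10; supply a custom RI for larger matrices")
  ri[n]
}

#' Consistency ratio CR = CI / RI
#'
#' Zero when RI is zero (orders 1 and 2 are always consistent).
#'
#' @param ci consistency index.
#' @param ri random index.
#' @return single numeric.
#' @export
consistencyRatio <- function(ci, ri) {
  if (ci < -1e-9 || ri < 0) stop("ci and ri must be non-negative")
  if (ri == 0) 0 else max(ci, 0) / ri
}

#' Full AHP analysis of a judgment matrix
#'
#' Derives weights, estimates lambda_max, computes CI, RI and CR, and flags
#' acceptance (CR < 0.1). A rejected matrix still returns its numbers so that
#' callers can report them and refuse downstream use.
#'
#' @inheritParams lambdaMax
#' @param ri random index override for n > 10.
#' @return A [ConsistencyReport-class].
#' @examples
#' rep <- ahpAnalyze(ricePairwiseMatrix())
#' rep
#' @export
ahpAnalyze <- function(matrix, method = c("rowmax", "rowmean", "eigen"),
                       ri = NULL) {
  method <- match.arg(method)
  w <- ahpWeights(matrix)
  n <- length(w)
  lm <- lambdaMax(matrix, w, method = method)
  ci <- consistencyIndex(lm, n)
  if (is.null(ri)) ri <- randomIndex(n)
  cr <- consistencyRatio(ci, ri)
  new("ConsistencyReport", weights = w, lambdaMax = lm, ci = ci, ri = ri,
      cr = cr, accepted = cr < 0.1, method = method)
}

setMethod("show", "ConsistencyReport", function(object) {
  cat(sprintf("ConsistencyReport (n = %d, lambda_max estimator '%s')\n",
              length(object@weights), object@method))
  w <- object@weights
  for (i in seq_along(w))
    cat(sprintf("  %-14s %.4f\n", names(w)[i], w[i]))
  cat(sprintf("  lambda_max = %.4f  CI = %.4f  RI = %.2f  CR = %.4f -> %s\n",
              object@lambdaMax, object@ci, object@ri, object@cr,
              if (object@accepted) "accepted (CR < 0.1)"
              else "REJECTED (CR >= 0.1)"))
})

#' Accessors for consistency reports
#'
#' @param report a [ConsistencyReport-class].
#' @return `reportWeights`: named weights; `reportCR`: the consistency ratio;
#'   `isAccepted`: logical acceptance flag.
#' @export
reportWeights <- function(report) report@weights

#' @rdname reportWeights
#' @export
reportCR <- function(report) report@cr

#' @rdname reportWeights
#' @export
isAccepted <- function(report) report@accepted

## ---------------------------------------------------------------------------
## Matrix and report I/O
## ---------------------------------------------------------------------------

#' Read / write a pairwise comparison matrix as labeled CSV
#'
#' Square CSV with criterion labels in the header row and first column.
#' On read, when `autoReciprocal = TRUE` only the upper triangle is used and
#' the lower triangle is filled with exact reciprocals.
#'
#' @param path CSV file path.
#' @param autoReciprocal see [pairwiseMatrix()].
#' @return A [PairwiseMatrix-class].
#' @export
readPairwiseMatrix <- function(path, autoReciprocal = FALSE) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  pairwiseMatrix(as.matrix(d), labels = rownames(d),
                 autoReciprocal = autoReciprocal)
}

#' @rdname readPairwiseMatrix
#' @param matrix a [PairwiseMatrix-class] to write.
#' @export
writePairwiseMatrix <- function(matrix, path) {
  utils::write.csv(as.data.frame(matrix@entries), path)
  invisible(path)
}

#' Write a consistency report as JSON
#'
#' @param report a [ConsistencyReport-class].
#' @param path output path.
#' @export
writeConsistencyReport <- function(report, path) {
  jsonlite::write_json(list(
    weights = as.list(report@weights),
    lambda_max = report@lambdaMax, ci = report@ci, ri = report@ri,
    cr = report@cr, accepted = report@accepted, method = report@method),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
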