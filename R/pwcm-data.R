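## Packaged criterion judgment matrices for the two crops. The upper
## triangle holds the elicited Saaty judgments; the lower triangle is filled
## with exact reciprocals (published renderings print them to two decimals).

#' Packaged criterion pairwise comparison matrices
#'
#' Expert judgment matrices over the nine suitability criteria for rice and
#' coconut. Rice favours rainfall and (imperfect) drainage most strongly;
#' coconut favours rainfall and temperature. Both matrices pass the CR < 0.1
#' consistency gate (CR = 0.0781 for rice and 0.0708 for coconut under the
#' default lambda_max estimator).
#'
#' @return A [PairwiseMatrix-class] over nine criteria.
#' @examples
#' round(ahpWeights(ricePairwiseMatrix()), 2)
#' @export
ricePairwiseMatrix <- function() {
  labels <- c("rainfall", "temperature", "drainage", "depth", "texture",
              "slope", "elevation", "soc", "ph")
  J <- rbind(
    c(1, 8, 1, 5, 3, 6, 6, 7, 9),
    c(0, 1, 0, 0, 0, 0, 0, 0, 2),
    c(1, 8, 1, 3, 2, 5, 5, 7, 9),
    c(0, 5, 0, 1, 0, 3, 3, 4, 7),
    c(0, 6, 0, 2, 1, 4, 4, 5, 7),
    c(0, 3, 0, 0, 0, 1, 1, 2, 5),
    c(0, 3, 0, 0, 0, 1, 1, 2, 5),
    c(0, 2, 0, 0, 0, 0, 0, 1, 3),
    c(0, 0, 0, 0, 0, 0, 0, 0, 1))
  # judgments where the row criterion dominates (entries >= 1); zeros become
  # exact reciprocals of the transposed entry
  A <- J
  for (i in 1:9) for (j in 1:9) {
    if (i == j) A[i, j] <- 1
    else if (J[i, j] == 0) A[i, j] <- 1 / J[j, i]
  }
  pairwiseMatrix(A, labels)
}

#' @rdname ricePairwiseMatrix
#' @export
coconutPairwiseMatrix <- function() {
  labels <- c("elevation", "slope", "depth", "texture", "drainage",
              "rainfall", "temperature", "ph", "soc")
  J <- rbind(
    c(1, 0, 0, 0, 0, 0, 0, 2, 3),
    c(2, 1, 0, 0, 0, 0, 0, 3, 5),
    c(5, 4, 1, 3, 2, 0, 0, 6, 7),
    c(3, 2, 0, 1, 0, 0, 0, 4, 5),
    c(4, 3, 0, 2, 1, 0, 0, 5, 7),
    c(7, 6, 3, 5, 4, 1, 2, 8, 9),
    c(6, 5, 2, 4, 3, 0, 1, 7, 8),
    c(0, 0, 0, 0, 0, 0, 0, 1, 2),
    c(0, 0, 0, 0, 0, 0, 0, 0, 1))
  A <- J
  for (i in 1:9) for (j in 1:9) {
    if (i == j) A[i, j] <- 1
    else if (J[i, j] == 0) A[i, j] <- 1 / J[j, i]
  }
  pairwiseMatrix(A, labels)
}

#' Full-precision criterion weights for a packaged crop
#'
#' Column-normalization weights of the packaged judgment matrix, in the
#' canonical criterion order used by the classification schemes.
#'
#' @param crop "rice" or "coconut".
#' @return named numeric weights summing to 1.
#' @export
cropCriterionWeights <- function(crop = c("rice", "coconut")) {
  crop <- match.arg(crop)
  m <- if (crop == "rice") ricePairwiseMatrix() else coconutPairwiseMatrix()
  ahpWeights(m)
}
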