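test_that("absence sampling avoids excluded classes and is seed-reproducible", {
  legend <- c("1" = "S1", "2" = "S2", "3" = "S3", "4" = "N")
  codes <- matrix(1L, 10, 10)
  codes[5, 7] <- 2L
  g <- categoricalGrid(codes, legend)
  # only one non-S1 cell: the draw is forced onto it
  a <- sampleAbsences(g, 1, seed = 3)
  expect_equal(cellIndex(g, a$x, a$y), data.frame(row = 5L, col = 7L))
  expect_error(sampleAbsences(g, 2, seed = 3), "eligible")
  # determinism under the same seed
  set.seed(99)  # outer RNG state must not leak in
  codes2 <- matrix(sample(1:4, 400, TRUE), 20)
  g2 <- categoricalGrid(codes2, legend)
  a1 <- sampleAbsences(g2, 50, seed = 11)
  a2 <- sampleAbsences(g2, 50, seed = 11)
  expect_identical(a1, a2)
  expect_false(identical(a1, sampleAbsences(g2, 50, seed = 12)))
  # no sampled point lies on an S1 cell; no duplicates
  idx <- cellIndex(g2, a1$x, a1$y)
  expect_true(all(codes2[cbind(idx$row, idx$col)] != 1L))
  expect_false(anyDuplicated(a1[, c("x", "y")]) > 0)
})

test_that("absence sampling on a masked map respects the non-cropland rule", {
  b <- sharedLandscape()
  res <- runPipeline(b, "rice")
  mc <- maskedClasses(res)
  a <- sampleAbsences(mc, 500, seed = 4)
  idx <- cellIndex(mc, a$x, a$y)
  lab <- gridLegend(mc)[as.character(gridValues(mc)[cbind(idx$row, idx$col)])]
  expect_false(any(lab %in% c("S1", "non-cropland")))
  aAll <- sampleAbsences(mc, 500, seed = 4, allowNoncropland = TRUE)
  idx2 <- cellIndex(mc, aAll$x, aAll$y)
  lab2 <- gridLegend(mc)[as.character(gridValues(mc)[cbind(idx2$row,
                                                           idx2$col)])]
  expect_false(any(lab2 == "S1"))
})

test_that("score extraction follows the half-open pixel convention", {
  g <- rasterGrid(matrix(1:16, 4), cellsize = 100)
  # cell centers
  sc <- extractScores(g, data.frame(x = 50, y = 350, label = "presence"))
  expect_equal(sc$score, g@values[1, 1])
  # x on a shared vertical edge goes to the eastern cell; y on a horizontal
  # edge goes to the cell below
  sc2 <- extractScores(g, data.frame(x = 100, y = 250, label = "presence"))
  expect_equal(sc2$score, g@values[2, 2])
  sc3 <- extractScores(g, data.frame(x = 50, y = 100, label = "presence"))
  expect_equal(sc3$score, g@values[4, 1])
  expect_error(extractScores(g, data.frame(x = -10, y = 50)), "outside")
  # nodata points are dropped with a message; all-nodata errors
  g2 <- g; g2@values[1, 1] <- NA
  expect_message(
    out <- extractScores(g2, data.frame(x = c(50, 150), y = c(350, 350))),
    "dropped 1")
  expect_equal(nrow(out), 1L)
  expect_error(extractScores(g2, data.frame(x = 50, y = 350)), "missing")
  # per-point indexing oracle on a seeded set
  set.seed(14)
  pts <- data.frame(x = runif(40, 0, 400), y = runif(40, 0, 400))
  got <- extractScores(g, pts)$score
  want <- vapply(seq_len(40), function(i) {
    col <- floor(pts$x[i] / 100) + 1
    row <- 4 - ceiling(pts$y[i] / 100) + 1
    g@values[row, col]
  }, numeric(1))
  expect_equal(got, want)
})

test_that("AUROC equals exhaustive pair counting with midrank ties", {
  r <- rocAuc(c(0.9, 0.8, 0.7, 0.6), c("presence", "absence", "presence",
                                       "absence"))
  expect_equal(r@auroc, 0.75)  # 3 of 4 pairs correctly ordered
  expect_equal(rocAuc(c(1, 2, 3, 10), c(FALSE, FALSE, TRUE, TRUE))@auroc, 1)
  expect_equal(rocAuc(rep(0.4, 6), rep(c(TRUE, FALSE), 3))@auroc, 0.5)
  # pair-counting oracle on seeded data with ties
  set.seed(15)
  score <- sample(seq(0, 1, 0.1), 60, TRUE)
  lab <- sample(c(TRUE, FALSE), 60, TRUE, prob = c(0.4, 0.6))
  pairs <- expand.grid(p = which(lab), a = which(!lab))
  oracle <- mean(ifelse(score[pairs$p] > score[pairs$a], 1,
                        ifelse(score[pairs$p] == score[pairs$a], 0.5, 0)))
  expect_equal(rocAuc(score, lab)@auroc, oracle)
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "both")
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(16)
  score <- c(rnorm(40, 1), rnorm(50))
  lab <- rep(c(TRUE, FALSE), c(40, 50))
  got <- rocAuc(score, lab)@auroc
  want <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = score,
                                         quiet = TRUE, direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("AUROC is rank-invariant and label-antisymmetric", {
  set.seed(17)
  score <- runif(80)
  lab <- score + rnorm(80, sd = 0.3) > 0.5
  if (all(lab) || !any(lab)) skip("degenerate draw")
  a0 <- rocAuc(score, lab)@auroc
  expect_equal(rocAuc(exp(5 * score), lab)@auroc, a0)   # monotone transform
  expect_equal(rocAuc(rank(score), lab)@auroc, a0)
  expect_equal(rocAuc(score, !lab)@auroc, 1 - a0)       # label swap
  # curve is a valid staircase
  r <- rocAuc(score, lab)
  expect_equal(r@tpr[1], 0); expect_equal(r@fpr[1], 0)
  expect_equal(r@tpr[length(r@tpr)], 1)
  expect_equal(r@fpr[length(r@fpr)], 1)
})

test_that("accuracy bands follow the conventional thresholds", {
  expect_equal(rocAuc(c(1, 2), c(FALSE, TRUE))@band, "very high")
  expect_equal(rocAuc(rep(1, 4), c(TRUE, FALSE, TRUE, FALSE))@band, "low")
  set.seed(18)
  s <- c(rnorm(200, 0.9), rnorm(200))
  expect_equal(rocAuc(s, rep(c(TRUE, FALSE), each = 200))@band, "high")
})

test_that("duplicate occurrence records are removed within labels", {
  pts <- data.frame(x = c(1, 1, 2, 1), y = c(1, 1, 2, 1),
                    label = c("presence", "presence", "presence", "absence"))
  occ <- occurrenceSet(pts)
  expect_equal(nrow(occurrencePoints(occ)), 3L)
  expect_equal(sum(occurrencePoints(occ)$label == "presence"), 2L)
})

test_that("area correlation matches the covariance formula and guards variance", {
  v <- c(10, 20, 30, 40)
  expect_equal(areaCorrelation(v, v), 1)
  expect_equal(areaCorrelation(v, rev(v)), -1)
  set.seed(19)
  a <- runif(12); b <- 0.6 * a + rnorm(12, sd = 0.1)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(areaCorrelation(a, b), oracle)
  expect_error(areaCorrelation(rep(1, 4), v), "variance")
  expect_error(areaCorrelation(1:2, 1:2), "3 paired")
})
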