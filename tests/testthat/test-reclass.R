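test_that("packaged schemes carry the published bins and weights", {
  rs <- riceScheme(); cs <- coconutScheme()
  expect_equal(unname(rs$elevation@weights),
               c(0.58, 0.26, 0.12, 0.05))
  expect_equal(rs$elevation@bins$upper, c(100, 500, 1000, Inf))
  expect_equal(unname(cs$rainfall@weights[c(">1500", "1000-1500",
                                            "500-1000", "<500")]),
               c(0.54, 0.29, 0.11, 0.06))
  expect_equal(unname(rs$depth@weights[c(">125", "100-125")]), c(0.28, 0.28))
  expect_equal(unname(cs$texture@weights["loam"]), 0.67)
  # every scheme: positive weights, sum ~1, 9 criteria per crop
  for (sch in c(rs, cs)) {
    expect_true(all(sch@weights > 0))
    expect_lt(abs(sum(sch@weights) - 1), 0.02 + 1e-12)
  }
  expect_setequal(names(rs), c("elevation", "slope", "depth", "texture",
                               "drainage", "soc", "ph", "rainfall",
                               "temperature"))
  expect_setequal(names(cs), names(rs))
})

test_that("every scheme footer satisfies the CI/CR arithmetic at printed precision", {
  for (crop in c("rice", "coconut")) {
    for (sch in cropScheme(crop)) {
      f <- sch@footer
      if (f["n"] >= 2) {
        ciRe <- consistencyIndex(f[["lambda_max"]], f[["n"]])
        expect_lt(abs(ciRe - f[["ci"]]), 1e-3)
        expect_lt(abs(consistencyRatio(ciRe, f[["ri"]]) - f[["cr"]]), 1e-3)
      }
      expect_lt(f[["cr"]], 0.1)  # all published subclass matrices accepted
    }
  }
})

test_that("interval reclassification maps values to the published bins", {
  rs <- riceScheme(); cs <- coconutScheme()
  g <- gridOf(c(50, 100, 250, 1500), units = "m")
  out <- reclassify(g, rs$elevation)
  expect_equal(as.vector(gridValues(out$weights)), c(0.58, 0.26, 0.26, 0.05))
  lab <- gridLegend(out$classes)[as.character(as.vector(gridValues(out$classes)))]
  # 100 m sits on the bin edge: lower-inclusive, so "100-500"
  expect_equal(unname(lab), c("<100", "100-500", "100-500", ">1000"))
  sl <- gridOf(c(5, 0.5, 31, 15), units = "%")
  expect_equal(as.vector(gridValues(reclassify(sl, cs$slope)$weights)),
               c(0.24, 0.51, 0.04, 0.06))
})

test_that("reclassification is exhaustive, exclusive and nodata-propagating", {
  rs <- riceScheme()
  set.seed(42)
  vals <- matrix(runif(100, 0, 2000), 10)
  vals[c(3, 50, 99)] <- NA
  g <- rasterGrid(vals, units = "m")
  out <- reclassify(g, rs$elevation)
  cls <- as.vector(gridValues(out$classes))
  w <- as.vector(gridValues(out$weights))
  expect_equal(is.na(cls), is.na(as.vector(vals)))
  expect_equal(is.na(w), is.na(as.vector(vals)))
  # bin counts sum to the non-missing cell count
  expect_equal(sum(table(cls)), sum(!is.na(vals)))
  # weight lookup round-trip: class code -> weight equals direct weight grid
  expect_equal(unname(rs$elevation@weights[cls[!is.na(cls)]]), w[!is.na(w)])
})

test_that("values outside a scheme domain fail loudly", {
  cs <- coconutScheme()
  g <- gridOf(c(27, 30), nrow = 1, units = "degC")  # 30 > top bin edge 29
  expect_error(reclassify(g, cs$temperature), "outside the scheme domain")
  # top boundary itself is absorbed by the extreme bin
  g2 <- gridOf(c(27, 29), nrow = 1, units = "degC")
  expect_equal(as.vector(gridValues(reclassify(g2, cs$temperature)$weights)),
               c(0.75, 0.75))
  # unit mismatch is refused
  g3 <- gridOf(c(27, 28), nrow = 1, units = "m")
  expect_error(reclassify(g3, cs$temperature), "units")
})

test_that("disjoint-interval pH subclasses reclassify symmetrically", {
  cs <- coconutScheme()
  g <- gridOf(c(4.7, 7.0, 4.2, 8.0, 5.5, 3.8), nrow = 1, units = "pH")
  out <- reclassify(g, cs$ph)
  expect_equal(as.vector(gridValues(out$weights)),
               c(0.27, 0.27, 0.11, 0.11, 0.57, 0.05))
})

test_that("categorical reclassification maps legend labels through the scheme", {
  rs <- riceScheme()
  legend <- c("1" = "clay", "2" = "loam", "3" = "sand", "4" = "silty clay")
  g <- categoricalGrid(matrix(c(1L, 2L, 3L, 4L), 2), legend)
  out <- reclassify(g, rs$texture)
  expect_equal(as.vector(gridValues(out$weights)), c(0.52, 0.22, 0.04, 0.52))
  bad <- categoricalGrid(matrix(1L), c("1" = "granite"))
  expect_error(reclassify(bad, rs$texture), "granite")
})

test_that("USDA texture classes match the triangle boundary table", {
  # hand-verified points of the 12-class triangle (sand, silt, clay)
  cases <- list(
    list(100, 0, 0, "sand"),
    list(85, 10, 5, "loamy sand"),
    list(65, 25, 10, "sandy loam"),
    list(40, 40, 20, "loam"),
    list(20, 65, 15, "silt loam"),
    list(5, 88, 7, "silt"),
    list(60, 10, 30, "sandy clay loam"),
    list(33, 34, 33, "clay loam"),
    list(10, 56, 34, "silty clay loam"),
    list(50, 8, 42, "sandy clay"),
    list(7, 48, 45, "silty clay"),
    list(20, 20, 60, "clay"))
  for (cse in cases)
    expect_equal(usdaTexture(cse[[1]], cse[[2]], cse[[3]]), cse[[4]])
  # renormalization within +/- 1 of 100 is accepted, farther is not
  expect_equal(usdaTexture(40.4, 40.3, 20.0), "loam")
  expect_error(usdaTexture(50, 50, 20), "sum")
  expect_error(usdaTexture(-5, 85, 20), "negative")
})

test_that("usdaTexture is exhaustive over the simplex", {
  pts <- expand.grid(sand = seq(0, 100, 4), clay = seq(0, 100, 4))
  pts <- pts[pts$sand + pts$clay <= 100, ]
  cls <- usdaTexture(pts$sand, 100 - pts$sand - pts$clay, pts$clay)
  expect_false(anyNA(cls))
  expect_true(all(cls %in% c("sand", "loamy sand", "sandy loam", "loam",
                             "silt loam", "silt", "sandy clay loam",
                             "clay loam", "silty clay loam", "sandy clay",
                             "silty clay", "clay")))
})

test_that("texture grouping follows the crop-specific memberships", {
  expect_equal(textureGroup("silty clay", "rice"), "clayey")
  expect_equal(textureGroup("silty clay", "coconut"), "SL, SiC, Si")
  expect_equal(textureGroup("loam", "coconut"), "loam")
  expect_equal(textureGroup("silt", "rice"), "loam")
  expect_equal(textureGroup(c("clay", "sand"), "rice"), c("clayey", "sand"))
  expect_error(textureGroup("peat", "rice"), "unknown")
})

test_that("depth-weighted averaging uses 5/15 and 10/15 thickness weights", {
  a <- gridOf(rep(7, 4)); b <- gridOf(rep(7, 4))
  expect_equal(as.vector(gridValues(depthWeightedAverage(a, b))), rep(7, 4))
  a2 <- gridOf(rep(3, 4)); b2 <- gridOf(rep(0, 4))
  expect_equal(as.vector(gridValues(depthWeightedAverage(a2, b2))), rep(1, 4))
  # per-cell loop oracle on random grids, with nodata propagation
  set.seed(7)
  m1 <- matrix(runif(30), 5); m2 <- matrix(runif(30), 5)
  m1[4] <- NA; m2[17] <- NA
  got <- gridValues(depthWeightedAverage(rasterGrid(m1), rasterGrid(m2)))
  want <- matrix(NA_real_, 5, 6)
  for (i in 1:5) for (j in 1:6)
    want[i, j] <- (5 * m1[i, j] + 10 * m2[i, j]) / 15
  expect_equal(got, want)
  # misaligned grids are refused
  expect_error(depthWeightedAverage(rasterGrid(m1), gridOf(1:4)),
               "co-registered")
})
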