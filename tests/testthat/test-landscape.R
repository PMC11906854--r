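test_that("the DEM is seed-deterministic and honours its range contract", {
  cfg <- landscapeConfig(rows = 32, cols = 32, seed = 5)
  d1 <- generateDEM(cfg)
  d2 <- generateDEM(cfg)
  expect_identical(gridValues(d1), gridValues(d2))
  expect_false(identical(gridValues(d1),
                         gridValues(generateDEM(landscapeConfig(rows = 32,
                                                                cols = 32,
                                                                seed = 6)))))
  expect_gte(min(gridValues(d1)), -5)
  expect_lte(max(gridValues(d1)), cfg$relief)
  # relief 0 collapses to the flat coastal floor
  flat <- generateDEM(landscapeConfig(rows = 32, cols = 32, relief = 0))
  expect_true(all(gridValues(flat) >= -5 & gridValues(flat) <= 0))
})

test_that("percent-rise slope is exact on planes and matches the stencil oracle", {
  flat <- rasterGrid(matrix(100, 5, 5), cellsize = 100)
  expect_equal(as.vector(gridValues(deriveSlope(flat))), rep(0, 25))
  # plane rising 1 m per 100 m eastward -> 1% everywhere (replicated edges)
  plane <- rasterGrid(outer(rep(0, 6), seq(0, 5, 1), "+"), cellsize = 100)
  sl <- gridValues(deriveSlope(plane))
  expect_equal(sl[, 2:5], matrix(1, 6, 4), ignore_attr = TRUE)
  # brute-force Horn stencil oracle on a seeded DEM (interior cells)
  set.seed(23)
  z <- matrix(rnorm(64, sd = 30), 8)
  dem <- rasterGrid(z, cellsize = 250)
  got <- gridValues(deriveSlope(dem))
  for (i in 2:7) for (j in 2:7) {
    dzdx <- ((z[i - 1, j + 1] + 2 * z[i, j + 1] + z[i + 1, j + 1]) -
             (z[i - 1, j - 1] + 2 * z[i, j - 1] + z[i + 1, j - 1])) / (8 * 250)
    dzdy <- ((z[i + 1, j - 1] + 2 * z[i + 1, j] + z[i + 1, j + 1]) -
             (z[i - 1, j - 1] + 2 * z[i - 1, j] + z[i - 1, j + 1])) / (8 * 250)
    expect_equal(got[i, j], 100 * sqrt(dzdx^2 + dzdy^2))
  }
  expect_true(all(got >= 0))
  expect_error(deriveSlope(rasterGrid(matrix(1, 2, 2))), "3 x 3")
})

test_that("generated layers obey their construction contracts", {
  cfg <- landscapeConfig(rows = 24, cols = 24, seed = 7, tempNoiseSd = 0)
  b <- generateLayers(cfg)
  # bit-identical regeneration under the same seed
  b2 <- generateLayers(cfg)
  expect_identical(gridValues(b$ph), gridValues(b2$ph))
  expect_identical(gridValues(b$lulc), gridValues(b2$lulc))
  # lapse rate: noise-free temperature differs by lapse * dz / 100
  tj <- gridValues(monthGrid(b$temperatureStack, 1))
  dz <- gridValues(b$dem)
  i <- which.max(dz); j <- which.min(dz)
  expect_equal(tj[i] - tj[j], -cfg$lapseRate * (dz[i] - dz[j]) / 100,
               tolerance = 1e-9)
  # particle-size fractions live on the simplex
  tot <- gridValues(b$sand) + gridValues(b$silt) + gridValues(b$clay)
  expect_equal(as.vector(tot), rep(100, 576), tolerance = 1e-9)
  # all layers co-registered with the DEM
  for (nm in c("slope", "depth", "ph", "soc", "rainfall",
               "temperatureRice", "temperatureCoconut")) {
    expect_true(sameGeometry(b[[nm]], b$dem))
  }
  expect_true(sameGeometry(b$lulc, b$dem))
})

test_that("generated layers fall inside both crops' scheme domains", {
  b <- sharedLandscape()
  for (crop in c("rice", "coconut")) {
    layers <- bundleToLayers(b, crop)
    for (nm in names(layers)) {
      expect_no_error(reclassify(layers[[nm]], cropScheme(crop)[[nm]]))
    }
  }
})

test_that("land cover is clumped, complete and close to the target mixture", {
  cfg <- landscapeConfig(seed = 9)
  l <- generateLULC(cfg)
  expect_setequal(unname(gridLegend(l)),
                  c("water", "trees", "flooded vegetation", "crops",
                    "built area", "bare ground", "snow/ice", "rangeland"))
  freq <- table(factor(gridValues(l), levels = names(gridLegend(l))))
  freq <- as.numeric(freq) / sum(freq)
  target <- unname(cfg$lulcMix[unname(gridLegend(l))])
  expect_true(all(abs(freq - target) <= 0.05))
  # degenerate mixture: everything crops
  mix <- setNames(rep(0, 8), names(cfg$lulcMix)); mix["crops"] <- 1
  expect_error(landscapeConfig(lulcMix = mix[1:7]), "8 land-cover")
  allCrops <- generateLULC(landscapeConfig(seed = 9, lulcMix = mix))
  expect_true(all(gridLegend(allCrops)[as.character(gridValues(allCrops))]
                  == "crops"))
})

test_that("occurrence generation responds to the suitability slope", {
  b <- sharedLandscape()
  cfg <- b$config
  res <- runPipeline(b, "rice")
  idx <- suitabilityIndex(res)
  v <- as.vector(gridValues(idx))
  # determinism
  o1 <- generateOccurrences(idx, cfg, 100)
  o2 <- generateOccurrences(idx, cfg, 100)
  expect_identical(occurrencePoints(o1), occurrencePoints(o2))
  # very steep slope: presences concentrate in the top index quartile
  oBig <- generateOccurrences(idx, cfg, 150, b = 80)
  sc <- extractScores(idx, occurrencePoints(oBig))
  q75 <- quantile(v, 0.75, na.rm = TRUE)
  expect_gte(mean(sc$score >= q75), 0.95)
  # no dependence: uniform over cells (chi-square on quadrant counts)
  o0 <- generateOccurrences(idx, cfg, 400, b = 0)
  p <- occurrencePoints(o0)
  ext <- 64 * 250
  quad <- paste(p$x > ext / 2, p$y > ext / 2)
  pval <- chisq.test(table(factor(quad, levels = c("FALSE FALSE",
                                                   "FALSE TRUE",
                                                   "TRUE FALSE",
                                                   "TRUE TRUE"))))$p.value
  expect_gt(pval, 0.01)
  expect_error(generateOccurrences(idx, landscapeConfig(occSlope = NULL), 10),
               "slope b")
})

test_that("the full synthetic pipeline completes quickly and coherently", {
  t0 <- Sys.time()
  b <- generateLandscape(landscapeConfig())
  res <- runPipeline(b, "rice")
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 5)
  bounds <- indexBounds(cropScheme("rice"))
  rng <- range(gridValues(suitabilityIndex(res)), na.rm = TRUE)
  expect_gte(rng[1], bounds[1]); expect_lte(rng[2], bounds[2])
  expect_equal(sum(areaTable(res)$area_pct), 100, tolerance = 0.01)
  expect_setequal(areaTable(res)$class,
                  c("S1", "S2", "S3", "N", "non-cropland"))
})
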