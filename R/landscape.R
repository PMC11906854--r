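## Seeded synthetic coastal landscape generator. Produces a miniature layer
## bundle with the statistical structure the analysis assumes (smooth DEM
## with derived slope, spatially autocorrelated soil and climate fields, a
## clumped 8-class land-cover map, and suitability-dependent occurrence
## points) so the whole pipeline runs without any downloads. Random fields
## are smoothed white noise (separable Gaussian kernel), chosen for
## simplicity over geostatistical fidelity; generated ranges are clipped to
## the packaged scheme domains so reclassification never faults. One global
## seed drives independent per-layer substreams, so adding a layer does not
## perturb the others.

#' Configuration for the synthetic coastal landscape
#'
#' Defaults emulate a small coastal strip: a 64 x 64 grid of 250 m cells
#' (16 km x 16 km), sea-level plain rising inland to ~1200 m, a wet-to-dry
#' rainfall gradient, a 0.6 degC / 100 m temperature lapse, and land cover
#' dominated by cropland. The occurrence model places presence probability
#' proportional to logistic(a + b z), where z is the standardized
#' suitability index; when `a` is `NULL` the logistic midpoint is placed at
#' the upper-quartile index boundary, so a large slope concentrates all
#' presences in the top index quartile.
#'
#' @param rows,cols grid shape (>= 8 each).
#' @param cellsize cell edge (m).
#' @param seed integer master seed.
#' @param relief maximum elevation (m); the coast sits at -5 m.
#' @param corLength autocorrelation length of the random fields (cells).
#' @param rainGradient rainfall increase per km inland-to-coast (mm/km).
#' @param rainBase annual rainfall at the dry edge (mm).
#' @param rainNoiseSd smoothed rainfall noise sd (mm).
#' @param lapseRate temperature lapse (degC per 100 m).
#' @param tempBase monthly sea-level temperature means, Jan..Dec (degC).
#' @param tempNoiseSd smoothed temperature noise sd (degC).
#' @param phMean,phSd soil pH field parameters.
#' @param socMean,socSd soil organic carbon field parameters (%).
#' @param depthMean,depthSd soil depth field parameters (cm).
#' @param lulcMix named land-cover mixture proportions over the 8 classes
#'   (must sum to 1).
#' @param occIntercept,occSlope occurrence model coefficients a and b.
#' @return validated list of class "landscapeConfig".
#' @export
landscapeConfig <- function(rows = 64, cols = 64, cellsize = 250, seed = 101,
                            relief = 1200, corLength = 6,
                            rainGradient = 125, rainBase = 600,
                            rainNoiseSd = 150,
                            lapseRate = 0.6,
                            tempBase = c(25.0, 26.0, 27.5, 29.0, 29.5, 28.5,
                                         27.5, 27.0, 27.5, 27.5, 26.0, 25.0),
                            tempNoiseSd = 0.3,
                            phMean = 6.3, phSd = 0.8,
                            socMean = 0.9, socSd = 0.45,
                            depthMean = 90, depthSd = 40,
                            lulcMix = c("crops" = 0.40, "rangeland" = 0.12,
                                        "flooded vegetation" = 0.06,
                                        "bare ground" = 0.05, "trees" = 0.20,
                                        "water" = 0.08, "built area" = 0.08,
                                        "snow/ice" = 0.01),
                            occIntercept = NULL, occSlope = 10) {
  if (rows < 8 || cols < 8) stop("grid must be at least 8 x 8")
  if (cellsize <= 0) stop("cellsize must be positive")
  if (length(tempBase) != 12) stop("tempBase needs 12 monthly values")
  if (abs(sum(lulcMix) - 1) > 1e-6)
    stop("land-cover mixture proportions must sum to 1")
  need <- c("water", "trees", "flooded vegetation", "crops", "built area",
            "bare ground", "snow/ice", "rangeland")
  if (!setequal(names(lulcMix), need))
    stop("lulcMix must cover exactly the 8 land-cover classes")
  structure(as.list(environment()), class = "landscapeConfig")
}

.lulcLegend <- function() {
  stats::setNames(c("water", "trees", "flooded vegetation", "crops",
                    "built area", "bare ground", "snow/ice", "rangeland"),
                  as.character(1:8))
}

# slice a continuous field into classes at exactly the target proportions:
# ranks are cut at the cumulative class counts, so class k occupies the cells
# whose field rank falls in its share (spatially clumped for smooth fields)
.rankSlice <- function(field, props) {
  r <- rank(field, ties.method = "first")
  cuts <- round(cumsum(props) * length(field))
  as.integer(findInterval(r - 0.5, cuts) + 1L)
}

# white noise field under a per-layer substream of the master seed
.noiseField <- function(config, offset, sigma = NULL) {
  if (is.null(sigma)) sigma <- config$corLength / 3
  withSeed(config$seed + offset,
           gaussSmooth(matrix(stats::rnorm(config$rows * config$cols),
                              config$rows, config$cols), sigma))
}

#' Generate the synthetic digital elevation model
#'
#' A smoothed random field blended with a west-to-east coastal gradient
#' (low near the western edge), squared to skew mass toward the lowlands of
#' a coastal plain, then rescaled to [-5, relief]. Deterministic under the
#' configured seed.
#'
#' @param config a [landscapeConfig()].
#' @return elevation [RasterGrid-class] (m).
#' @export
generateDEM <- function(config) {
  f <- rescaleTo(.noiseField(config, 1L), 0, 1)
  grad <- matrix(rep((seq_len(config$cols) - 0.5) / config$cols,
                     each = config$rows), config$rows, config$cols)
  e <- (0.35 * f + 0.65 * grad)^2
  rasterGrid(rescaleTo(e, -5, config$relief), 0, 0, config$cellsize,
             units = "m")
}

#' Percent-rise slope from a DEM
#'
#' 3 x 3 finite-difference slope (Horn's weights) in percent rise,
#' 100 * sqrt((dz/dx)^2 + (dz/dy)^2). Edge cells use one-sided differences
#' via edge replication. Exact for an inclined plane.
#'
#' @param dem elevation [RasterGrid-class] (>= 3 x 3).
#' @return slope [RasterGrid-class] (%).
#' @export
deriveSlope <- function(dem) {
  z <- dem@values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("DEM must be at least 3 x 3")
  cs <- dem@cellsize
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  a <- zp[i - 1, j - 1]; b <- zp[i - 1, j]; cc <- zp[i - 1, j + 1]
  d <- zp[i, j - 1];                        f <- zp[i, j + 1]
  g <- zp[i + 1, j - 1]; h <- zp[i + 1, j]; k <- zp[i + 1, j + 1]
  dzdx <- ((cc + 2 * f + k) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((g + 2 * h + k) - (a + 2 * b + cc)) / (8 * cs)
  rasterGrid(100 * sqrt(dzdx^2 + dzdy^2), dem@xll, dem@yll, cs, units = "%")
}

#' Generate the co-registered environmental layer bundle
#'
#' Produces every layer the suitability schemes consume, co-registered with
#' the DEM: monthly temperature (seasonal cycle minus lapse * elevation/100
#' plus smoothed noise) and rainfall stacks (coastal gradient plus noise,
#' spread over a monsoonal monthly profile), smoothed soil pH / SOC / depth
#' fields, spatially coherent categorical drainage, sand/silt/clay simplex
#' fields with the derived USDA texture classes, and the criterion layers
#' (annual rainfall, growing-season and annual mean temperature) derived
#' from the stacks. Values are clipped to the packaged scheme domains
#' (pH <= 8.5, annual mean temperature <= 29 degC).
#'
#' @param config a [landscapeConfig()].
#' @param dem optional precomputed DEM (regenerated when NULL).
#' @return named list: dem, slope, depth, ph, soc, sand, silt, clay,
#'   texture (USDA [CategoricalGrid-class]), drainage, temperatureStack,
#'   rainfallStack, rainfall (annual, mm), temperatureRice (JJAS mean),
#'   temperatureCoconut (annual mean), lulc, config.
#' @export
generateLayers <- function(config, dem = NULL) {
  if (is.null(dem)) dem <- generateDEM(config)
  nr <- config$rows; nc <- config$cols; cs <- config$cellsize
  mkGrid <- function(m, units = "") rasterGrid(m, 0, 0, cs, units)

  ## temperature: seasonal cycle - lapse + smooth spatial noise (per month)
  tnoise <- .noiseField(config, 2L)
  tnoise <- tnoise / max(stats::sd(tnoise), 1e-9) * config$tempNoiseSd
  tgrids <- lapply(1:12, function(m)
    mkGrid(config$tempBase[m] - config$lapseRate * dem@values / 100 + tnoise,
           "degC"))
  tstack <- monthlyStack(tgrids, "temperature", "degC")

  ## rainfall: annual total with inland gradient + noise, spread monthly
  kmFromEast <- matrix(rep((config$cols - seq_len(nc) + 0.5) * cs / 1000,
                           each = nr), nr, nc)
  rnoise <- .noiseField(config, 3L)
  rnoise <- rnoise / max(stats::sd(rnoise), 1e-9) * config$rainNoiseSd
  annual <- pmax(config$rainBase + config$rainGradient * kmFromEast + rnoise,
                 50)
  profile <- c(1, 1, 1, 2, 4, 14, 22, 20, 14, 12, 6, 3)
  profile <- profile / sum(profile)
  rgrids <- lapply(1:12, function(m) mkGrid(annual * profile[m], "mm"))
  rstack <- monthlyStack(rgrids, "precipitation", "mm")

  ## smoothed soil fields, clipped to scheme domains
  normField <- function(offset, mean, sd, lo, hi) {
    f <- .noiseField(config, offset)
    f <- f / max(stats::sd(f), 1e-9) * sd + mean
    mkGrid(pmin(pmax(f, lo), hi))
  }
  ph <- normField(4L, config$phMean, config$phSd, 3.5, 8.5)
  ph@units <- "pH"
  soc <- normField(5L, config$socMean, config$socSd, 0.05, 3)
  soc@units <- "%"
  depth <- normField(6L, config$depthMean, config$depthSd, 5, 160)
  depth@units <- "cm"

  ## drainage: quantile-sliced smooth field -> 6 spatially coherent classes
  drainLabels <- c("well drained", "moderately well drained", "imperfect",
                   "poor", "very poor", "excessive")
  drainProps <- c(0.30, 0.15, 0.25, 0.12, 0.08, 0.10)
  df <- .noiseField(config, 7L)
  dcodes <- matrix(.rankSlice(df, drainProps), nr, nc)
  drainage <- categoricalGrid(dcodes,
                              stats::setNames(drainLabels,
                                              as.character(1:6)),
                              0, 0, cs)

  ## texture: simplex fields by softmax of three smooth fields
  fs <- .noiseField(config, 8L) + 0.3   # sand
  fi <- .noiseField(config, 9L)         # silt
  fc <- .noiseField(config, 10L) + 0.4  # clay
  es <- exp(2 * fs); ei <- exp(2 * fi); ec <- exp(2 * fc)
  tot <- es + ei + ec
  sand <- mkGrid(100 * es / tot, "%")
  silt <- mkGrid(100 * ei / tot, "%")
  clay <- mkGrid(100 * ec / tot, "%")
  classes <- sort(unique(as.vector(
    usdaTexture(sand@values, silt@values, clay@values))))
  tex <- usdaTexture(sand@values, silt@values, clay@values)
  texture <- categoricalGrid(matrix(match(tex, classes), nr, nc),
                             stats::setNames(classes,
                                             as.character(seq_along(classes))),
                             0, 0, cs)

  ## derived criterion layers
  tempRice <- seasonMean(tstack, 6:9)
  tempCoco <- seasonMean(tstack, 1:12)
  tempCoco@values <- pmin(tempCoco@values, 29)
  rainfall <- annualPrecip(rstack)

  list(dem = dem, slope = deriveSlope(dem), depth = depth, ph = ph,
       soc = soc, sand = sand, silt = silt, clay = clay, texture = texture,
       drainage = drainage, temperatureStack = tstack,
       rainfallStack = rstack, rainfall = rainfall,
       temperatureRice = tempRice, temperatureCoconut = tempCoco,
       lulc = generateLULC(config), config = config)
}

#' Generate a clumped 8-class land-cover map
#'
#' Slices a smoothed random field at the cumulative mixture proportions, so
#' class frequencies match the configured proportions (up to ties) and
#' classes form spatial clumps.
#'
#' @param config a [landscapeConfig()].
#' @return A [CategoricalGrid-class] over the 8 land-cover classes.
#' @export
generateLULC <- function(config) {
  legend <- .lulcLegend()
  mix <- config$lulcMix[unname(legend)]
  f <- .noiseField(config, 11L)
  codes <- matrix(.rankSlice(f, mix), config$rows, config$cols)
  categoricalGrid(codes, legend, 0, 0, config$cellsize)
}

#' Generate presence points from a suitability index
#'
#' Samples `n` presence cells without replacement with probability
#' proportional to logistic(a + b z), z the standardized index over
#' non-missing cells. With `a = NULL` the midpoint sits at the standardized
#' upper-quartile boundary, so as b grows all presences concentrate in the
#' top index quartile; b = 0 gives spatially uniform presences.
#'
#' @param index suitability [RasterGrid-class].
#' @param config a [landscapeConfig()] carrying the coefficients and seed.
#' @param n number of presence points.
#' @param b slope override; defaults to `config$occSlope`. Must be supplied
#'   one way or the other.
#' @param seed seed override; defaults to `config$seed`.
#' @return An [OccurrenceSet-class] of presences at cell centers.
#' @export
generateOccurrences <- function(index, config, n, b = NULL, seed = NULL) {
  if (is.null(b)) b <- config$occSlope
  if (is.null(b)) stop("occurrence slope b must be specified")
  if (n < 1) stop("n must be at least 1")
  if (is.null(seed)) seed <- config$seed
  v <- as.vector(index@values)
  ok <- which(!is.na(v))
  if (length(ok) < n) stop("not enough non-missing cells")
  z <- (v[ok] - mean(v[ok])) / max(stats::sd(v[ok]), 1e-12)
  a <- config$occIntercept
  if (is.null(a)) a <- -b * stats::quantile(z, 0.75)
  p <- stats::plogis(a + b * z)
  pick <- ok[withSeed(seed + 13L, sample(length(ok), n, prob = p))]
  nr <- nrow(index@values)
  row <- ((pick - 1L) %% nr) + 1L
  col <- ((pick - 1L) %/% nr) + 1L
  cs <- index@cellsize
  occurrenceSet(data.frame(
    x = index@xll + (col - 0.5) * cs,
    y = index@yll + (nr - row + 0.5) * cs,
    label = "presence", stringsAsFactors = FALSE),
    note = sprintf("synthetic, b = %g", b))
}

#' One-call synthetic landscape bundle
#'
#' @param config a [landscapeConfig()].
#' @return the [generateLayers()] bundle.
#' @export
generateLandscape <- function(config = landscapeConfig()) {
  generateLayers(config)
}
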