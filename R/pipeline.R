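## End-to-end pipeline: consistency gate -> reclassify -> overlay ->
## classify -> mask -> areas, with a machine-readable run manifest.

#' Assemble crop criterion layers from a landscape bundle
#'
#' Maps a [generateLayers()] bundle (or any list using its names) onto the
#' nine criterion layers a crop scheme set expects: the DEM supplies
#' elevation, and the temperature criterion uses the June-September
#' growing-season mean for rice and the annual mean for coconut.
#'
#' @param bundle layer bundle from [generateLayers()].
#' @param crop "rice" or "coconut".
#' @return named list of criterion layers for [suitabilityAnalysis()].
#' @export
bundleToLayers <- function(bundle, crop = c("rice", "coconut")) {
  crop <- match.arg(crop)
  list(elevation = bundle$dem, slope = bundle$slope, depth = bundle$depth,
       texture = bundle$texture, drainage = bundle$drainage,
       soc = bundle$soc, ph = bundle$ph, rainfall = bundle$rainfall,
       temperature = if (crop == "rice") bundle$temperatureRice
                     else bundle$temperatureCoconut)
}

#' Run the full suitability pipeline and write its outputs
#'
#' Executes the complete analysis for one crop on a prepared layer bundle:
#' AHP analysis of the criterion matrix with the CR < 0.1 gate,
#' reclassification of all nine criterion layers, weighted overlay,
#' equal-interval classification, land-cover constraint masking and area
#' tabulation. All intermediates and a JSON manifest (weights, consistency
#' numbers, class breaks, seed, package version) are written to `outDir`
#' when given. The pipeline is a pure function of its inputs: re-running the
#' same configuration reproduces the area table exactly.
#'
#' @param bundle layer bundle ([generateLayers()] output or equivalent).
#' @param crop "rice" or "coconut".
#' @param outDir output directory (created); NULL skips writing.
#' @param matrix optional [PairwiseMatrix-class] criterion matrix override.
#' @param schemes optional scheme-set override.
#' @param force proceed despite a failed consistency gate (recorded in the
#'   manifest).
#' @param seed seed recorded in the manifest (the scoring chain itself is
#'   deterministic).
#' @return A [SuitabilityResult-class]; the manifest list is attached as
#'   attribute "manifest".
#' @export
runPipeline <- function(bundle, crop = c("rice", "coconut"), outDir = NULL,
                        matrix = NULL, schemes = NULL, force = FALSE,
                        seed = NULL) {
  crop <- match.arg(crop)
  layers <- bundleToLayers(bundle, crop)
  constraint <- if (!is.null(bundle$lulc)) constraintMap(bundle$lulc)
                else NULL
  result <- suitabilityAnalysis(layers, crop, constraint = constraint,
                                matrix = matrix, schemes = schemes,
                                force = force)
  report <- result@consistency
  manifest <- list(
    crop = crop,
    criterion_weights = as.list(round(result@criterionWeights, 6)),
    lambda_max = report@lambdaMax, ci = report@ci, ri = report@ri,
    cr = report@cr, consistency_accepted = report@accepted,
    forced = force && !report@accepted,
    breaks = result@breaks,
    index_range = as.numeric(range(result@index@values, na.rm = TRUE)),
    seed = seed,
    package_version = as.character(utils::packageVersion("CropSuit")))
  attr(result, "manifest") <- manifest
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeAsciiGrid(result@index, file.path(outDir, "index.asc"))
    writeCategoricalGrid(result@classes, file.path(outDir, "classes.asc"))
    writeCategoricalGrid(result@maskedClasses,
                         file.path(outDir, "classes_masked.asc"))
    utils::write.csv(result@areas, file.path(outDir, "areas.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
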