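## Weighted overlay scoring, equal-interval classification, constraint
## masking and area tabulation.

.CLASS_LABELS <- c("S1", "S2", "S3", "N")
.MASK_LABEL <- "non-cropland"

#' Weighted overlay of subclass-weight layers
#'
#' Cell-wise suitability index S = sum_i W_i * w_i(cell), where W_i is the
#' AHP criterion weight and w_i(cell) the subclass weight of criterion i at
#' the cell (from [reclassify()]). Missing in any layer propagates.
#'
#' @param weightLayers named list of co-registered [RasterGrid-class]
#'   subclass-weight layers, one per criterion.
#' @param criterionWeights named numeric AHP weights; names must match the
#'   layer names and the weights must sum to 1 (1e-6 tolerance).
#' @return A [RasterGrid-class] suitability index (dimensionless).
#' @export
weightedOverlay <- function(weightLayers, criterionWeights) {
  if (abs(sum(criterionWeights) - 1) > 1e-6)
    stop("criterion weights must sum to 1")
  missing <- setdiff(names(criterionWeights), names(weightLayers))
  if (length(missing) > 0L)
    stop(sprintf("missing criterion layer(s): %s",
                 paste(missing, collapse = ", ")))
  g1 <- weightLayers[[names(criterionWeights)[1]]]
  acc <- matrix(0, nrow(g1@values), ncol(g1@values))
  for (nm in names(criterionWeights)) {
    g <- weightLayers[[nm]]
    .stopIfMisaligned(g, g1, sprintf("criterion layer '%s'", nm))
    acc <- acc + criterionWeights[[nm]] * g@values
  }
  rasterGrid(acc, g1@xll, g1@yll, g1@cellsize, units = "")
}

#' Equal-interval classification of a suitability index
#'
#' Splits the observed (non-missing) index range into `nClasses` intervals of
#' identical width and labels them from the top down: the highest interval is
#' S1 (highly suitable), then S2 (moderately), S3 (marginally) and N (not
#' suitable). A value lying exactly on an interior break goes to the upper
#' class; the maximum goes to S1. Breaks derive from the observed min/max,
#' not from theoretical index bounds.
#'
#' @param index a [RasterGrid-class] with at least one non-missing cell.
#' @param nClasses number of classes (default 4).
#' @return list with `classes` (a [CategoricalGrid-class], codes 1 = S1 ...
#'   4 = N) and `breaks` (ascending interior break values, length
#'   `nClasses - 1`).
#' @examples
#' idx <- rasterGrid(matrix(seq(0, 1, length.out = 16), 4))
#' equalIntervalClassify(idx)$breaks   # 0.25 0.50 0.75
#' @export
equalIntervalClassify <- function(index, nClasses = 4) {
  v <- index@values
  if (all(is.na(v))) stop("index has no non-missing cells")
  lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
  if (hi - lo < 1e-12)
    stop("constant index: equal-interval classification is degenerate; check that the input layers vary")
  breaks <- lo + seq_len(nClasses - 1) * (hi - lo) / nClasses
  # number of interior breaks <= value, counted from the bottom; a value on a
  # break joins the class above it
  below <- findInterval(as.vector(v), breaks)  # 0..nClasses-1
  code <- nClasses - below                      # 1 = top class
  codes <- matrix(as.integer(code), nrow(v), ncol(v))
  codes[is.na(v)] <- NA_integer_
  labels <- if (nClasses == 4) .CLASS_LABELS else paste0("C", seq_len(nClasses))
  list(classes = categoricalGrid(codes,
                                 stats::setNames(labels,
                                                 as.character(seq_len(nClasses))),
                                 index@xll, index@yll, index@cellsize),
       breaks = breaks)
}

#' Build a land-cover constraint map
#'
#' @param lulc a [CategoricalGrid-class] of land-cover classes.
#' @param cropland labels treated as cultivable; default flooded vegetation,
#'   crops, bare ground and rangeland.
#' @param noncropland labels masked out; default water, trees, built area and
#'   snow/ice. Together the two sets must partition the legend.
#' @return A [ConstraintMap-class].
#' @export
constraintMap <- function(lulc,
                          cropland = c("flooded vegetation", "crops",
                                       "bare ground", "rangeland"),
                          noncropland = c("water", "trees", "built area",
                                          "snow/ice")) {
  new("ConstraintMap", lulc = lulc, cropland = cropland,
      noncropland = noncropland)
}

#' Mask non-cropland cells out of a suitability classification
#'
#' Cells whose land cover falls in the non-cropland set are recoded to a
#' dedicated "non-cropland" class; all other cells keep their suitability
#' class. The cell count is conserved, so before/after area tables remain
#' directly comparable.
#'
#' @param classes suitability [CategoricalGrid-class] (from
#'   [equalIntervalClassify()]).
#' @param constraint a [ConstraintMap-class] co-registered with `classes`.
#' @return A [CategoricalGrid-class] with the extra non-cropland class.
#' @export
applyConstraint <- function(classes, constraint) {
  stopifnot(is(constraint, "ConstraintMap"))
  lulc <- constraint@lulc
  .stopIfMisaligned(classes, lulc, "suitability classes and land cover")
  lab <- unname(lulc@legend[as.character(as.vector(lulc@codes))])
  known <- is.na(lab) | lab %in% c(constraint@cropland, constraint@noncropland)
  if (!all(known))
    stop(sprintf("land-cover class '%s' missing from the constraint partition",
                 lab[which(!known)[1]]))
  codes <- classes@codes
  maskCode <- max(as.integer(names(classes@legend))) + 1L
  recode <- matrix(lab %in% constraint@noncropland,
                   nrow(codes), ncol(codes))
  codes[recode & !is.na(codes)] <- maskCode
  legend <- c(classes@legend, stats::setNames(.MASK_LABEL,
                                              as.character(maskCode)))
  categoricalGrid(codes, legend, classes@xll, classes@yll, classes@cellsize)
}

#' Tabulate class areas
#'
#' Hectares per class from the cell count and the square cell size
#' (count * cellsize^2 / 10000); percentages are relative to all non-missing
#' cells and sum to 100. Every legend class gets a row, including empty ones.
#'
#' @param classes a [CategoricalGrid-class].
#' @return data.frame with columns class, cells, area_ha, area_pct.
#' @export
tabulateAreas <- function(classes) {
  codes <- as.vector(classes@codes)
  counts <- table(factor(codes, levels = names(classes@legend)))
  cells <- as.integer(counts)
  ha <- cells * classes@cellsize^2 / 1e4
  total <- sum(ha)
  data.frame(class = unname(classes@legend),
             cells = cells,
             area_ha = ha,
             area_pct = if (total > 0) 100 * ha / total else 0 * ha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score, classify, mask and tabulate in one call
#'
#' Runs the full scoring chain for one crop on a prepared layer bundle:
#' AHP consistency gate on the criterion matrix, per-criterion
#' reclassification, weighted overlay, equal-interval classification,
#' optional land-cover masking, and area tabulation. Refuses to run when the
#' criterion matrix fails the CR < 0.1 gate unless `force = TRUE`.
#'
#' @param layers named list of criterion layers matching the scheme set:
#'   continuous [RasterGrid-class] for interval schemes, categorical for
#'   categorical schemes.
#' @param crop "rice" or "coconut" (selects packaged matrix and schemes).
#' @param constraint optional [ConstraintMap-class]; when NULL, the masked
#'   map equals the unmasked one.
#' @param matrix optional [PairwiseMatrix-class] overriding the packaged
#'   criterion matrix.
#' @param schemes optional scheme list overriding the packaged one.
#' @param force run even when the consistency gate fails.
#' @return A [SuitabilityResult-class].
#' @export
suitabilityAnalysis <- function(layers, crop = c("rice", "coconut"),
                                constraint = NULL, matrix = NULL,
                                schemes = NULL, force = FALSE) {
  crop <- match.arg(crop)
  if (is.null(matrix))
    matrix <- if (crop == "rice") ricePairwiseMatrix()
              else coconutPairwiseMatrix()
  if (is.null(schemes)) schemes <- cropScheme(crop)
  report <- ahpAnalyze(matrix)
  if (!isAccepted(report) && !force)
    stop(sprintf(
      "criterion matrix rejected (CR = %.4f >= 0.1); use force = TRUE to override",
      reportCR(report)))
  W <- reportWeights(report)
  missing <- setdiff(names(schemes), names(layers))
  if (length(missing) > 0L)
    stop(sprintf("missing criterion layer(s): %s",
                 paste(missing, collapse = ", ")))
  wl <- lapply(names(schemes), function(nm)
    reclassify(layers[[nm]], schemes[[nm]])$weights)
  names(wl) <- names(schemes)
  index <- weightedOverlay(wl, W[names(schemes)])
  cls <- equalIntervalClassify(index)
  masked <- if (is.null(constraint)) cls$classes
            else applyConstraint(cls$classes, constraint)
  new("SuitabilityResult", crop = crop, index = index,
      classes = cls$classes, maskedClasses = masked, breaks = cls$breaks,
      areas = tabulateAreas(masked), criterionWeights = W,
      consistency = report)
}

setMethod("show", "SuitabilityResult", function(object) {
  rng <- range(object@index@values, na.rm = TRUE)
  cat(sprintf("SuitabilityResult for %s\n", object@crop))
  cat(sprintf("  index range [%.3f, %.3f], breaks %s\n", rng[1], rng[2],
              paste(sprintf("%.4f", object@breaks), collapse = ", ")))
  cat(sprintf("  criterion CR = %.4f (%s)\n", object@consistency@cr,
              if (object@consistency@accepted) "accepted" else "rejected"))
  print(object@areas, digits = 4)
})

#' Accessors for suitability results
#'
#' @param result a [SuitabilityResult-class].
#' @return `suitabilityIndex`: the index grid; `suitabilityClasses`: the
#'   unmasked class grid; `maskedClasses`: the masked class grid;
#'   `areaTable`: the area table; `classBreaks`: interior break values.
#' @export
suitabilityIndex <- function(result) result@index

#' @rdname suitabilityIndex
#' @export
suitabilityClasses <- function(result) result@classes

#' @rdname suitabilityIndex
#' @export
maskedClasses <- function(result) result@maskedClasses

#' @rdname suitabilityIndex
#' @export
areaTable <- function(result) result@areas

#' @rdname suitabilityIndex
#' @export
classBreaks <- function(result) result@breaks

#' Theoretical index bounds of a scheme set
#'
#' The smallest and largest achievable index values: the criterion-weighted
#' sums of the minimum and maximum subclass weights. Any observed index range
#' must lie inside these bounds.
#'
#' @param schemes a scheme list from [cropScheme()].
#' @param criterionWeights named AHP weights (defaults to the weights stored
#'   on the schemes).
#' @return numeric length-2 (min, max).
#' @export
indexBounds <- function(schemes, criterionWeights = NULL) {
  if (is.null(criterionWeights))
    criterionWeights <- vapply(schemes, slot, numeric(1), "criterionWeight")
  lo <- sum(vapply(names(schemes), function(nm)
    criterionWeights[[nm]] * min(schemes[[nm]]@weights), numeric(1)))
  hi <- sum(vapply(names(schemes), function(nm)
    criterionWeights[[nm]] * max(schemes[[nm]]@weights), numeric(1)))
  c(lo, hi)
}
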