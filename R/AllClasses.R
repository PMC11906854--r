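#' @import methods
NULL

## ---------------------------------------------------------------------------
## Pairwise comparison matrix (Saaty scale)
## ---------------------------------------------------------------------------

#' Pairwise comparison matrix on the Saaty 1/9..9 scale
#'
#' An n x n positive reciprocal judgment matrix over named criteria. Judgment
#' matrices are elicited on Saaty's scale: a_ij = 9 means criterion i is
#' extremely more important than j, a_ij = 1 equal importance, and the lower
#' triangle holds the reciprocals. Because published matrices typically print
#' reciprocals to two decimals (0.13 for 1/8), reciprocity is enforced within
#' a 5 percent relative tolerance rather than exactly.
#'
#' @slot entries numeric matrix of judgments; diagonal exactly 1.
#' @slot labels character vector of criterion names (row/column order).
#'
#' @seealso [pairwiseMatrix()], [ahpAnalyze()]
#' @export
setClass("PairwiseMatrix",
  representation(entries = "matrix", labels = "character"))

setValidity("PairwiseMatrix", function(object) {
  A <- object@entries
  n <- nrow(A)
  if (!is.numeric(A) || n != ncol(A))
    return("entries must be a square numeric matrix")
  if (n < 2L || n > 15L)
    return("matrix order must be between 2 and 15")
  if (length(object@labels) != n)
    return("labels length must equal matrix order")
  bad <- which(!is.finite(A) | A <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    return(sprintf("non-positive or non-finite judgment at [%d, %d]",
                   bad[1, 1], bad[1, 2]))
  if (any(abs(diag(A) - 1) > 1e-12))
    return("diagonal entries must equal 1 exactly")
  # reciprocity within 5% relative tolerance (printed 2-decimal reciprocals)
  rel <- abs(A * t(A) - 1)
  bad <- which(rel > 0.05, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    return(sprintf(
      "reciprocity violated beyond tolerance at [%d, %d]: %g vs %g",
      bad[1, 1], bad[1, 2], A[bad[1, 1], bad[1, 2]], A[bad[1, 2], bad[1, 1]]))
  TRUE
})

## ---------------------------------------------------------------------------
## Consistency report
## ---------------------------------------------------------------------------

#' AHP consistency report
#'
#' Weights and consistency diagnostics for a [PairwiseMatrix-class]. A matrix
#' is accepted when its consistency ratio CR = CI/RI falls below 0.1; a
#' rejected matrix still carries its numbers so callers can report them and
#' refuse downstream use.
#'
#' @slot weights named numeric vector summing to 1.
#' @slot lambdaMax maximum-eigenvalue estimate (>= n for reciprocal matrices).
#' @slot ci consistency index (lambdaMax - n)/(n - 1).
#' @slot ri random consistency index for the matrix order.
#' @slot cr consistency ratio ci/ri (0 when ri = 0).
#' @slot accepted logical, cr < 0.1.
#' @slot method lambdaMax estimator used ("rowmax", "rowmean" or "eigen").
#'
#' @export
setClass("ConsistencyReport",
  representation(weights = "numeric", lambdaMax = "numeric", ci = "numeric",
                 ri = "numeric", cr = "numeric", accepted = "logical",
                 method = "character"))

setValidity("ConsistencyReport", function(object) {
  w <- object@weights
  if (any(w <= 0)) return("all weights must be positive")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1")
  n <- length(w)
  if (object@lambdaMax < n - 1e-9)
    return("lambdaMax below matrix order: not a reciprocal-matrix estimate")
  TRUE
})

## ---------------------------------------------------------------------------
## Grids
## ---------------------------------------------------------------------------

#' Continuous raster layer
#'
#' A rectangular field of values on a square-celled grid. Row 1 of the value
#' matrix is the northernmost row; `xll`/`yll` give the lower-left corner of
#' the grid in projected map units (metres). Missing cells are `NA`.
#'
#' @slot values numeric matrix (row 1 = top).
#' @slot xll,yll numeric lower-left corner coordinates (m).
#' @slot cellsize numeric cell edge length (m), > 0.
#' @slot units character value units (e.g. "m", "%", "mm").
#'
#' @seealso [rasterGrid()], [readAsciiGrid()]
#' @export
setClass("RasterGrid",
  representation(values = "matrix", xll = "numeric", yll = "numeric",
                 cellsize = "numeric", units = "character"))

setValidity("RasterGrid", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (length(object@cellsize) != 1L || !is.finite(object@cellsize) ||
      object@cellsize <= 0)
    return("cellsize must be a single positive number")
  if (length(object@xll) != 1L || length(object@yll) != 1L)
    return("xll and yll must be single numbers")
  TRUE
})

#' Categorical raster layer
#'
#' Integer-coded categorical field (land cover, drainage class, suitability
#' class...). Every non-`NA` code must appear in the legend.
#'
#' @slot codes integer matrix (row 1 = top), `NA` for missing.
#' @slot legend named character vector mapping code (name) to label.
#' @slot xll,yll,cellsize grid geometry as in [RasterGrid-class].
#'
#' @export
setClass("CategoricalGrid",
  representation(codes = "matrix", legend = "character", xll = "numeric",
                 yll = "numeric", cellsize = "numeric"))

setValidity("CategoricalGrid", function(object) {
  if (length(object@cellsize) != 1L || object@cellsize <= 0)
    return("cellsize must be a single positive number")
  if (is.null(names(object@legend)) || anyDuplicated(names(object@legend)))
    return("legend must have unique code names")
  used <- unique(as.vector(object@codes))
  used <- used[!is.na(used)]
  if (!all(as.character(used) %in% names(object@legend)))
    return("codes present in the grid are missing from the legend")
  TRUE
})

## ---------------------------------------------------------------------------
## Classification scheme
## ---------------------------------------------------------------------------

#' Per-criterion subclass classification scheme
#'
#' Maps a criterion layer to ordered suitability subclasses, each carrying the
#' AHP subclass weight. Interval schemes bin a continuous layer (lower bound
#' inclusive, upper exclusive; the extreme bins absorb their outer boundary);
#' a subclass may span several disjoint intervals (e.g. a pH class grouping
#' mildly alkaline with moderately acidic soils). Categorical schemes map
#' category labels to subclasses. The footer records the consistency
#' diagnostics of the subclass judgment matrix as published (the matrices
#' themselves live in supplementary material and are not reconstructed).
#'
#' @slot criterion character criterion name.
#' @slot units character layer units ("" for categorical).
#' @slot kind "interval" or "categorical".
#' @slot bins data.frame; interval: (label, lower, upper), possibly several
#'   rows per label; categorical: (label, category) one row per member
#'   category.
#' @slot weights named numeric subclass weight per label.
#' @slot footer named numeric (n, lambda_max, ci, ri, cr) of the subclass
#'   judgment matrix.
#' @slot criterionWeight numeric criterion-level AHP weight.
#'
#' @seealso [riceScheme()], [coconutScheme()], [reclassify()]
#' @export
setClass("ClassificationScheme",
  representation(criterion = "character", units = "character",
                 kind = "character", bins = "data.frame",
                 weights = "numeric", footer = "numeric",
                 criterionWeight = "numeric"))

setValidity("ClassificationScheme", function(object) {
  if (!object@kind %in% c("interval", "categorical"))
    return("kind must be 'interval' or 'categorical'")
  if (is.null(names(object@weights)))
    return("weights must be named by subclass label")
  if (!all(unique(object@bins$label) %in% names(object@weights)))
    return("every bin label needs a subclass weight")
  if (any(object@weights <= 0)) return("subclass weights must be positive")
  if (abs(sum(object@weights) - 1) > 0.02)
    return("subclass weights must sum to 1 within 0.02 (printed rounding)")
  if (object@kind == "interval") {
    b <- object@bins[order(object@bins$lower), , drop = FALSE]
    if (any(b$upper <= b$lower)) return("interval bins must have upper > lower")
    if (nrow(b) > 1L &&
        any(abs(b$lower[-1] - b$upper[-nrow(b)]) > 1e-9))
      return("interval bins must be contiguous and non-overlapping")
  }
  need <- c("n", "lambda_max", "ci", "ri", "cr")
  if (!all(need %in% names(object@footer)))
    return("footer must contain n, lambda_max, ci, ri, cr")
  TRUE
})

## ---------------------------------------------------------------------------
## Monthly climatology stack
## ---------------------------------------------------------------------------

#' Stack of 12 monthly climatology layers
#'
#' @slot grids list of 12 co-registered [RasterGrid-class] objects, January
#'   to December.
#' @slot variable character variable name ("temperature", "precipitation").
#' @slot units character ("degC" or "mm").
#'
#' @export
setClass("MonthlyStack",
  representation(grids = "list", variable = "character", units = "character"))

setValidity("MonthlyStack", function(object) {
  if (length(object@grids) != 12L) return("a stack holds exactly 12 months")
  if (!all(vapply(object@grids, is, logical(1), "RasterGrid")))
    return("all stack members must be RasterGrid")
  g1 <- object@grids[[1]]
  ok <- vapply(object@grids, function(g) sameGeometry(g, g1), logical(1))
  if (!all(ok)) return("all 12 months must be co-registered")
  TRUE
})

## ---------------------------------------------------------------------------
## Constraint map, occurrences, ROC, suitability result
## ---------------------------------------------------------------------------

#' Land-cover constraint map
#'
#' A categorical land-cover grid together with a binary partition of its
#' legend into cropland (cultivable) and non-cropland (permanently excluded)
#' classes. The default partition places flooded vegetation, crops, bare
#' ground and rangeland in cropland, and water, trees, built area and
#' snow/ice in non-cropland.
#'
#' @slot lulc [CategoricalGrid-class] of land-cover codes.
#' @slot cropland character labels treated as cultivable.
#' @slot noncropland character labels masked out.
#'
#' @export
setClass("ConstraintMap",
  representation(lulc = "CategoricalGrid", cropland = "character",
                 noncropland = "character"))

setValidity("ConstraintMap", function(object) {
  leg <- unname(object@lulc@legend)
  both <- c(object@cropland, object@noncropland)
  if (anyDuplicated(both)) return("cropland/non-cropland sets overlap")
  if (!setequal(both, leg))
    return("cropland and non-cropland sets must partition the legend")
  TRUE
})

#' Presence/absence occurrence records
#'
#' @slot points data.frame with columns x, y (map units) and label
#'   ("presence" or "absence").
#' @slot note character free-text provenance note.
#'
#' @export
setClass("OccurrenceSet",
  representation(points = "data.frame", note = "character"))

setValidity("OccurrenceSet", function(object) {
  p <- object@points
  if (!all(c("x", "y", "label") %in% names(p)))
    return("points needs columns x, y, label")
  if (!all(p$label %in% c("presence", "absence")))
    return("labels must be 'presence' or 'absence'")
  for (lab in unique(p$label)) {
    q <- p[p$label == lab, c("x", "y")]
    if (anyDuplicated(q)) return(sprintf("duplicate coordinates within %s", lab))
  }
  TRUE
})

#' ROC curve and AUROC
#'
#' @slot thresholds numeric score thresholds of the sweep.
#' @slot tpr,fpr numeric true/false positive rates along the curve.
#' @slot auroc numeric area under the curve (Mann-Whitney, midrank ties).
#' @slot band character accuracy band ("very high" > 0.9, "high" 0.7-0.9,
#'   "low" < 0.7).
#' @slot nPresence,nAbsence integer class sizes.
#'
#' @export
setClass("RocResult",
  representation(thresholds = "numeric", tpr = "numeric", fpr = "numeric",
                 auroc = "numeric", band = "character",
                 nPresence = "integer", nAbsence = "integer"))

setValidity("RocResult", function(object) {
  if (object@auroc < 0 || object@auroc > 1) return("auroc must lie in [0, 1]")
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    return("tpr and fpr must be non-decreasing along the curve")
  TRUE
})

#' Suitability analysis result
#'
#' Holds the weighted-overlay suitability index, its four-class equal-interval
#' classification (S1 highly, S2 moderately, S3 marginally, N not suitable),
#' the constraint-masked classification (adding a non-cropland class), the
#' class breaks and the area table.
#'
#' @slot crop character crop name.
#' @slot index [RasterGrid-class] suitability index.
#' @slot classes [CategoricalGrid-class] 4-class map.
#' @slot maskedClasses [CategoricalGrid-class] masked map (may be the same as
#'   `classes` when no constraint was applied).
#' @slot breaks numeric interior class breaks (length 3).
#' @slot areas data.frame (class, area_ha, area_pct) for the masked map.
#' @slot criterionWeights named numeric AHP criterion weights used.
#' @slot consistency [ConsistencyReport-class] of the criterion matrix.
#'
#' @export
setClass("SuitabilityResult",
  representation(crop = "character", index = "RasterGrid",
                 classes = "CategoricalGrid", maskedClasses = "CategoricalGrid",
                 breaks = "numeric", areas = "data.frame",
                 criterionWeights = "numeric",
                 consistency = "ConsistencyReport"))
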