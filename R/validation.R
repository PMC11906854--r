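## Presence/absence validation: absence sampling, score extraction,
## ROC/AUROC and the acreage correlation utility.

#' Create an occurrence set
#'
#' @param points data.frame with columns x, y, label ("presence"/"absence").
#'   Duplicate coordinates within a label are removed (exact match), mirroring
#'   standard occurrence-record cleaning.
#' @param note provenance note.
#' @return An [OccurrenceSet-class].
#' @export
occurrenceSet <- function(points, note = "") {
  keep <- !duplicated(points[, c("x", "y", "label")])
  new("OccurrenceSet", points = points[keep, , drop = FALSE], note = note)
}

#' @rdname occurrenceSet
#' @param x an [OccurrenceSet-class].
#' @export
occurrencePoints <- function(x) x@points

setMethod("show", "OccurrenceSet", function(object) {
  tab <- table(object@points$label)
  cat(sprintf("OccurrenceSet: %d presence, %d absence%s\n",
              sum(object@points$label == "presence"),
              sum(object@points$label == "absence"),
              if (nzchar(object@note)) paste0(" (", object@note, ")") else ""))
  invisible(tab)
})

#' Sample random absence points
#'
#' Draws `n` points uniformly at random over eligible cells of a classified
#' suitability map, at cell centers, without replacement. Eligible cells
#' exclude the highly suitable class (absences are sampled "leaving highly
#' suitable areas"), missing cells, and by default also masked non-cropland
#' cells so that absences stay comparable to the mapped suitability surface;
#' set `allowNoncropland = TRUE` to allow absences on non-cropland.
#'
#' @param classes a [CategoricalGrid-class] (masked or unmasked).
#' @param n number of absences.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param excludeClasses class labels never sampled.
#' @param allowNoncropland drop "non-cropland" from the exclusion set.
#' @return data.frame (x, y, label = "absence").
#' @export
sampleAbsences <- function(classes, n, seed,
                           excludeClasses = c("S1", "non-cropland"),
                           allowNoncropland = FALSE) {
  if (n < 1) stop("n must be at least 1")
  if (allowNoncropland)
    excludeClasses <- setdiff(excludeClasses, "non-cropland")
  lab <- unname(classes@legend[as.character(as.vector(classes@codes))])
  eligible <- which(!is.na(lab) & !(lab %in% excludeClasses))
  if (length(eligible) < n)
    stop(sprintf("only %d eligible cells for %d absences",
                 length(eligible), n))
  pick <- eligible[withSeed(seed, sample.int(length(eligible), n))]
  # map linear column-major cell index back to row/col, then to centers
  nr <- nrow(classes@codes)
  row <- ((pick - 1L) %% nr) + 1L
  col <- ((pick - 1L) %/% nr) + 1L
  cs <- classes@cellsize
  data.frame(x = classes@xll + (col - 0.5) * cs,
             y = classes@yll + (nr - row + 0.5) * cs,
             label = "absence", stringsAsFactors = FALSE)
}

#' Extract suitability scores at point locations
#'
#' Looks up the index value of the cell containing each point (half-open
#' pixel convention, see [cellIndex()]). Points falling on missing cells are
#' dropped with a message; points outside the extent are an error.
#'
#' @param index a [RasterGrid-class].
#' @param points data.frame with columns x, y and (optionally) label.
#' @return data.frame (x, y, label, score) for retained points.
#' @export
extractScores <- function(index, points) {
  idx <- cellIndex(index, points$x, points$y)
  if (anyNA(idx$row))
    stop(sprintf("%d point(s) fall outside the grid extent",
                 sum(is.na(idx$row))))
  score <- index@values[cbind(idx$row, idx$col)]
  drop <- is.na(score)
  if (all(drop)) stop("all points fall on missing cells")
  if (any(drop))
    message(sprintf("dropped %d point(s) on missing cells", sum(drop)))
  out <- points[!drop, , drop = FALSE]
  out$score <- score[!drop]
  out
}

#' ROC curve and AUROC for presence/absence scores
#'
#' AUROC is computed as the Mann-Whitney rank statistic U / (n1 n2) with
#' midrank handling of ties (so all-tied scores give exactly 0.5); the curve
#' comes from a threshold sweep over the unique scores. The accuracy band
#' follows the conventional reading: above 0.9 very high, 0.7-0.9 high,
#' below 0.7 low.
#'
#' @param score numeric suitability scores.
#' @param label character "presence"/"absence" (or logical presence flags).
#' @return A [RocResult-class].
#' @examples
#' rocAuc(c(0.9, 0.8, 0.7, 0.6),
#'        c("presence", "absence", "presence", "absence"))@auroc  # 0.75
#' @export
rocAuc <- function(score, label) {
  if (is.logical(label)) label <- ifelse(label, "presence", "absence")
  pos <- label == "presence"
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L)
    stop("both presence and absence scores are required")
  r <- rank(score)  # midranks
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(score[pos] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(score[!pos] >= t) / n2, numeric(1))
  band <- if (auc > 0.9) "very high" else if (auc >= 0.7) "high" else "low"
  new("RocResult", thresholds = thr, tpr = tpr, fpr = fpr, auroc = auc,
      band = band, nPresence = as.integer(n1), nAbsence = as.integer(n2))
}

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUROC = %.3f (%s accuracy), %d presence / %d absence\n",
              object@auroc, object@band, object@nPresence, object@nAbsence))
})

#' Validate a suitability map against occurrence records
#'
#' Convenience wrapper: samples absences on the classified map, extracts
#' index scores for presences and absences, and computes the ROC.
#'
#' @param index suitability index [RasterGrid-class].
#' @param classes classified map used for absence eligibility.
#' @param presences data.frame (x, y) of presence records.
#' @param seed integer seed for the absence draw.
#' @inheritParams sampleAbsences
#' @return A [RocResult-class].
#' @export
validateSuitability <- function(index, classes, presences, seed,
                                allowNoncropland = FALSE) {
  pres <- data.frame(x = presences$x, y = presences$y, label = "presence",
                     stringsAsFactors = FALSE)
  abs <- sampleAbsences(classes, nrow(pres), seed,
                        allowNoncropland = allowNoncropland)
  occ <- occurrenceSet(rbind(pres, abs))
  sc <- extractScores(index, occurrencePoints(occ))
  rocAuc(sc$score, sc$label)
}

#' Pearson correlation of predicted vs observed acreage
#'
#' Correlates model-predicted suitable areas with observed cultivated areas
#' over paired reporting units (districts).
#'
#' @param predicted,observed numeric vectors of paired areas (>= 3 pairs).
#' @return single numeric Pearson R.
#' @export
areaCorrelation <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3L)
    stop("at least 3 paired areas required")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    stop("zero variance in one of the area vectors")
  stats::cor(predicted, observed)
}

#' Write an ROC summary as JSON
#'
#' @param roc a [RocResult-class].
#' @param path output path.
#' @export
writeRocSummary <- function(roc, path) {
  jsonlite::write_json(list(auroc = roc@auroc, band = roc@band,
                            n_presence = roc@nPresence,
                            n_absence = roc@nAbsence),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
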