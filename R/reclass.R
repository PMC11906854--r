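## Reclassification of environmental layers into subclass-weight layers,
## plus soil preprocessing (depth-weighted averaging, USDA texture classing).

#' Reclassify a layer through a classification scheme
#'
#' Maps every non-missing cell to exactly one subclass and returns both the
#' subclass map and the grid of subclass weights. Interval schemes take a
#' [RasterGrid-class]; categorical schemes take a [CategoricalGrid-class]
#' whose legend labels appear among the scheme's categories. Values outside
#' the scheme's declared domain raise an error (the packaged schemes were
#' built to span the study region's observed ranges; silent clamping would
#' hide unit mistakes). Missing cells propagate to both outputs.
#'
#' @param layer input grid.
#' @param scheme a [ClassificationScheme-class].
#' @return list with elements `classes` ([CategoricalGrid-class], coded in
#'   scheme label order) and `weights` ([RasterGrid-class]).
#' @examples
#' g <- rasterGrid(matrix(c(50, 250, 800, 1500), 2), units = "m")
#' reclassify(g, riceScheme()$elevation)$weights
#' @export
reclassify <- function(layer, scheme) {
  stopifnot(is(scheme, "ClassificationScheme"))
  labels <- names(scheme@weights)
  if (scheme@kind == "interval") {
    if (!is(layer, "RasterGrid"))
      stop("interval schemes reclassify a RasterGrid")
    if (nzchar(scheme@units) && nzchar(layer@units) &&
        !identical(scheme@units, layer@units))
      stop(sprintf("layer units '%s' do not match scheme units '%s'",
                   layer@units, scheme@units))
    v <- layer@values
    b <- scheme@bins[order(scheme@bins$lower), , drop = FALSE]
    lo <- b$lower[1]; hi <- b$upper[nrow(b)]
    vv <- as.vector(v)
    bad <- !is.na(vv) & (vv < lo - 1e-9 | vv > hi + 1e-9)
    if (any(bad))
      stop(sprintf(
        "value %g of criterion '%s' outside the scheme domain [%g, %g]",
        vv[which(bad)[1]], scheme@criterion, lo, hi))
    idx <- findInterval(vv, b$lower)          # lower-inclusive
    idx[!is.na(vv) & vv >= hi] <- nrow(b)     # top bin absorbs its boundary
    code <- match(b$label[idx], labels)
    code[is.na(vv)] <- NA_integer_
  } else {
    if (!is(layer, "CategoricalGrid"))
      stop("categorical schemes reclassify a CategoricalGrid")
    v <- layer@codes
    vv <- as.vector(v)
    cellLabel <- unname(layer@legend[as.character(vv)])
    known <- cellLabel %in% scheme@bins$category
    if (any(!is.na(vv) & !known))
      stop(sprintf("category '%s' is not in the '%s' scheme domain (%s)",
                   cellLabel[which(!is.na(vv) & !known)[1]],
                   scheme@criterion,
                   paste(unique(scheme@bins$category), collapse = ", ")))
    binLabel <- scheme@bins$label[match(cellLabel, scheme@bins$category)]
    code <- match(binLabel, labels)
    code[is.na(vv)] <- NA_integer_
  }
  codes <- matrix(as.integer(code), nrow(v), ncol(v))
  legend <- stats::setNames(labels, as.character(seq_along(labels)))
  wgrid <- matrix(unname(scheme@weights)[code], nrow(v), ncol(v))
  list(
    classes = categoricalGrid(codes, legend, layer@xll, layer@yll,
                              layer@cellsize),
    weights = rasterGrid(wgrid, layer@xll, layer@yll, layer@cellsize,
                         units = ""))
}

#' USDA soil texture class from sand/silt/clay fractions
#'
#' Implements the twelve-class USDA texture triangle from particle-size
#' fractions in percent. Fractions are renormalized when their sum is within
#' 100 +/- 1; a sum farther from 100 or any negative fraction is an error.
#' Vectorized.
#'
#' @param sand,silt,clay fractions in percent.
#' @return character vector of USDA class names (lower case, e.g. "loam",
#'   "silty clay loam").
#' @examples
#' usdaTexture(40, 40, 20)   # "loam"
#' usdaTexture(20, 20, 60)   # "clay"
#' @export
usdaTexture <- function(sand, silt, clay) {
  n <- max(length(sand), length(silt), length(clay))
  sand <- rep_len(sand, n); silt <- rep_len(silt, n); clay <- rep_len(clay, n)
  if (any(sand < 0 | silt < 0 | clay < 0, na.rm = TRUE))
    stop("negative particle-size fraction")
  tot <- sand + silt + clay
  if (any(abs(tot - 100) > 1, na.rm = TRUE))
    stop(sprintf("fractions sum to %g; expected 100 +/- 1",
                 tot[which(abs(tot - 100) > 1)[1]]))
  sand <- 100 * sand / tot; silt <- 100 * silt / tot; clay <- 100 * clay / tot
  out <- character(n)
  for (i in seq_len(n)) {
    s <- sand[i]; si <- silt[i]; c <- clay[i]
    if (is.na(s) || is.na(si) || is.na(c)) { out[i] <- NA_character_; next }
    out[i] <-
      if (si + 1.5 * c < 15) "sand"
      else if (si + 2 * c < 30) "loamy sand"
      else if ((c >= 7 && c < 20 && s > 52) || (c < 7 && si < 50)) "sandy loam"
      else if (c >= 7 && c < 27 && si >= 28 && si < 50 && s <= 52) "loam"
      else if (si >= 50 && ((c >= 12 && c < 27) || (si < 80 && c < 12)))
        "silt loam"
      else if (si >= 80 && c < 12) "silt"
      else if (c >= 20 && c < 35 && si < 28 && s > 45) "sandy clay loam"
      else if (c >= 27 && c < 40 && s > 20 && s <= 45) "clay loam"
      else if (c >= 27 && c < 40 && s <= 20) "silty clay loam"
      else if (c >= 35 && s > 45) "sandy clay"
      else if (c >= 40 && si >= 40) "silty clay"
      else "clay"
  }
  out
}

#' Crop-specific grouped texture class
#'
#' Collapses the twelve USDA classes into the grouped classes used by the
#' crop schemes: for rice, clayey / loam / sandy loam / loamy sand / sand;
#' for coconut, loam / "SL, SiC, Si" / "S, C, LS".
#'
#' @param class USDA class name(s) from [usdaTexture()].
#' @param crop "rice" or "coconut".
#' @return character vector of grouped labels.
#' @export
textureGroup <- function(class, crop = c("rice", "coconut")) {
  crop <- match.arg(crop)
  sch <- cropScheme(crop)$texture
  out <- sch@bins$label[match(class, sch@bins$category)]
  if (any(is.na(out) & !is.na(class)))
    stop(sprintf("unknown USDA texture class '%s'",
                 class[which(is.na(out) & !is.na(class))[1]]))
  out
}

#' Depth-weighted 0-15 cm average of two soil layers
#'
#' Combines a 0-5 cm and a 5-15 cm layer into a 0-15 cm value with weights
#' proportional to layer thickness: (5 v05 + 10 v515) / 15. Missing in
#' either input propagates.
#'
#' @param layer05 [RasterGrid-class] for 0-5 cm.
#' @param layer515 [RasterGrid-class] for 5-15 cm.
#' @return [RasterGrid-class].
#' @export
depthWeightedAverage <- function(layer05, layer515) {
  .stopIfMisaligned(layer05, layer515, "soil depth layers")
  rasterGrid((5 * layer05@values + 10 * layer515@values) / 15,
             layer05@xll, layer05@yll, layer05@cellsize,
             units = layer05@units)
}
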