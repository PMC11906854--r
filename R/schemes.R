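## Packaged per-crop subclass classification schemes. Bin boundaries,
## subclass weights and the consistency footers of the subclass judgment
## matrices are packaged as published; the subclass matrices themselves are
## not reconstructed. Interval bins are lower-inclusive / upper-exclusive,
## with the extreme bins absorbing their outer boundary.

.scheme <- function(criterion, units, kind, bins, weights, footer, cw) {
  new("ClassificationScheme", criterion = criterion, units = units,
      kind = kind, bins = bins, weights = weights,
      footer = c(n = footer[1], lambda_max = footer[2], ci = footer[3],
                 ri = footer[4], cr = footer[5]),
      criterionWeight = unname(cw))
}

.intervalBins <- function(labels, edges) {
  data.frame(label = labels, lower = edges[-length(edges)], upper = edges[-1],
             stringsAsFactors = FALSE)
}

.catBins <- function(groups) {
  data.frame(label = rep(names(groups), lengths(groups)),
             category = unlist(groups, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Packaged classification schemes for rice and coconut
#'
#' Nine criterion schemes per crop: elevation (m), slope (percent rise),
#' soil depth (cm), soil texture (grouped USDA classes), soil drainage,
#' soil organic carbon (%), soil pH, annual (coconut) or growing-season
#' rainfall class driver (annual rainfall, mm) and temperature (growing
#' season mean for rice, annual mean for coconut, degC). Each scheme carries
#' its subclass weights, the published consistency footer of the subclass
#' judgment matrix, and the criterion-level AHP weight from the packaged
#' criterion matrix.
#'
#' Rice-specific notes: soil depth is weighted almost flat across the two
#' deepest classes (0.28 each, as published); the clayey texture group is
#' preferred (standing water). Coconut pH groups non-adjacent intervals
#' symmetric around the 5.0-6.5 optimum, so those subclasses span disjoint
#' interval pieces.
#'
#' @return named list of nine [ClassificationScheme-class] objects.
#' @examples
#' riceScheme()$elevation
#' @export
riceScheme <- function() {
  W <- cropCriterionWeights("rice")
  list(
    elevation = .scheme("elevation", "m", "interval",
      .intervalBins(c("<100", "100-500", "500-1000", ">1000"),
                    c(-Inf, 100, 500, 1000, Inf)),
      c("<100" = 0.58, "100-500" = 0.26, "500-1000" = 0.12, ">1000" = 0.05),
      c(4, 4.140, 0.047, 0.900, 0.052), W["elevation"]),
    slope = .scheme("slope", "%", "interval",
      .intervalBins(c("<1", "1-3", "3-10", "10-15", ">15"),
                    c(-Inf, 1, 3, 10, 15, Inf)),
      c("<1" = 0.51, "1-3" = 0.24, "3-10" = 0.14, "10-15" = 0.06,
        ">15" = 0.04),
      c(5, 5.326, 0.081, 1.12, 0.073), W["slope"]),
    depth = .scheme("depth", "cm", "interval",
      .intervalBins(c("<10", "10-25", "25-50", "50-75", "75-100", "100-125",
                      ">125"),
                    c(-Inf, 10, 25, 50, 75, 100, 125, Inf)),
      c("<10" = 0.02, "10-25" = 0.03, "25-50" = 0.06, "50-75" = 0.12,
        "75-100" = 0.20, "100-125" = 0.28, ">125" = 0.28),
      c(7, 7.409, 0.068, 1.32, 0.052), W["depth"]),
    texture = .scheme("texture", "", "categorical",
      .catBins(list(
        clayey = c("clay", "silty clay", "clay loam", "silty clay loam",
                   "sandy clay"),
        loam = c("sandy clay loam", "silt loam", "loam", "silt"),
        "sandy loam" = "sandy loam",
        "loamy sand" = "loamy sand",
        sand = "sand")),
      c(clayey = 0.52, loam = 0.22, "sandy loam" = 0.11, "loamy sand" = 0.10,
        sand = 0.04),
      c(5, 5.108, 0.027, 1.12, 0.024), W["texture"]),
    drainage = .scheme("drainage", "", "categorical",
      .catBins(list(
        imperfect = "imperfect", "very poor" = "very poor", poor = "poor",
        "moderately well drained" = "moderately well drained",
        "well drained" = "well drained", excessive = "excessive")),
      c(imperfect = 0.39, "very poor" = 0.28, poor = 0.18,
        "moderately well drained" = 0.08, "well drained" = 0.05,
        excessive = 0.03),
      c(6, 6.293, 0.059, 1.24, 0.047), W["drainage"]),
    soc = .scheme("soc", "%", "interval",
      .intervalBins(c("<0.25", "0.25-0.50", "0.50-0.75", "0.75-1.00",
                      ">1.00"),
                    c(-Inf, 0.25, 0.50, 0.75, 1.00, Inf)),
      c("<0.25" = 0.04, "0.25-0.50" = 0.07, "0.50-0.75" = 0.14,
        "0.75-1.00" = 0.31, ">1.00" = 0.43),
      c(5, 5.133, 0.033, 1.12, 0.030), W["soc"]),
    ph = .scheme("ph", "pH", "interval",
      .intervalBins(c("<4.5", "4.5-5.5", "5.5-6.5", "6.5-7.5", "7.5-8.5"),
                    c(-Inf, 4.5, 5.5, 6.5, 7.5, 8.5)),
      c("<4.5" = 0.09, "4.5-5.5" = 0.20, "5.5-6.5" = 0.46, "6.5-7.5" = 0.20,
        "7.5-8.5" = 0.04),
      c(5, 5.222, 0.055, 1.12, 0.049), W["ph"]),
    rainfall = .scheme("rainfall", "mm", "interval",
      .intervalBins(c("<750", "750-900", "900-1100", ">1100"),
                    c(-Inf, 750, 900, 1100, Inf)),
      c("<750" = 0.06, "750-900" = 0.11, "900-1100" = 0.29, ">1100" = 0.54),
      c(4, 4.009, 0.003, 0.900, 0.003), W["rainfall"]),
    temperature = .scheme("temperature", "degC", "interval",
      .intervalBins(c("<15", "15-20", "20-25", "25-30", ">30"),
                    c(-Inf, 15, 20, 25, 30, Inf)),
      c("<15" = 0.04, "15-20" = 0.06, "20-25" = 0.15, "25-30" = 0.27,
        ">30" = 0.48),
      c(5, 5.239, 0.060, 1.12, 0.053), W["temperature"]))
}

#' @rdname riceScheme
#' @export
coconutScheme <- function() {
  W <- cropCriterionWeights("coconut")
  phBins <- data.frame(
    label = c("<4.0", "7.5-8.5, 4.0-4.5", "6.5-7.5, 4.5-5.0", "5.0-6.5",
              "6.5-7.5, 4.5-5.0", "7.5-8.5, 4.0-4.5"),
    lower = c(-Inf, 4.0, 4.5, 5.0, 6.5, 7.5),
    upper = c(4.0, 4.5, 5.0, 6.5, 7.5, 8.5),
    stringsAsFactors = FALSE)
  list(
    elevation = .scheme("elevation", "m", "interval",
      .intervalBins(c("<100", "100-600", "600-900", ">900"),
                    c(-Inf, 100, 600, 900, Inf)),
      c("<100" = 0.58, "100-600" = 0.26, "600-900" = 0.12, ">900" = 0.05),
      c(4, 4.140, 0.047, 0.9, 0.052), W["elevation"]),
    slope = .scheme("slope", "%", "interval",
      .intervalBins(c("<4", "4-8", "8-15", "15-30", ">30"),
                    c(-Inf, 4, 8, 15, 30, Inf)),
      c("<4" = 0.51, "4-8" = 0.24, "8-15" = 0.14, "15-30" = 0.06,
        ">30" = 0.04),
      c(5, 5.326, 0.081, 1.12, 0.073), W["slope"]),
    depth = .scheme("depth", "cm", "interval",
      .intervalBins(c("<50", "50-75", "75-100", ">100"),
                    c(-Inf, 50, 75, 100, Inf)),
      c("<50" = 0.06, "50-75" = 0.12, "75-100" = 0.30, ">100" = 0.52),
      c(4, 4.118, 0.039, 0.9, 0.044), W["depth"]),
    texture = .scheme("texture", "", "categorical",
      .catBins(list(
        loam = c("clay loam", "loam", "sandy clay loam", "sandy clay",
                 "silty clay loam", "silt loam"),
        "SL, SiC, Si" = c("sandy loam", "silty clay", "silt"),
        "S, C, LS" = c("sand", "clay", "loamy sand"))),
      c(loam = 0.67, "SL, SiC, Si" = 0.24, "S, C, LS" = 0.09),
      c(3, 3.014, 0.007, 0.58, 0.012), W["texture"]),
    drainage = .scheme("drainage", "", "categorical",
      .catBins(list(
        "well drained" = "well drained",
        "moderately well drained" = "moderately well drained",
        imperfect = "imperfect", excessive = "excessive",
        "poorly drained" = c("poor", "very poor"))),
      c("well drained" = 0.49, "moderately well drained" = 0.24,
        imperfect = 0.12, excessive = 0.10, "poorly drained" = 0.04),
      c(5, 5.371, 0.093, 1.12, 0.083), W["drainage"]),
    soc = .scheme("soc", "%", "interval",
      .intervalBins(c("<0.25", "0.25-0.50", "0.50-0.75", "0.75-1.00",
                      ">1.00"),
                    c(-Inf, 0.25, 0.50, 0.75, 1.00, Inf)),
      c("<0.25" = 0.04, "0.25-0.50" = 0.07, "0.50-0.75" = 0.14,
        "0.75-1.00" = 0.31, ">1.00" = 0.43),
      c(5, 5.133, 0.033, 1.12, 0.030), W["soc"]),
    ph = .scheme("ph", "pH", "interval", phBins,
      c("5.0-6.5" = 0.57, "6.5-7.5, 4.5-5.0" = 0.27,
        "7.5-8.5, 4.0-4.5" = 0.11, "<4.0" = 0.05),
      c(4, 4.191, 0.064, 0.9, 0.071), W["ph"]),
    rainfall = .scheme("rainfall", "mm", "interval",
      .intervalBins(c("<500", "500-1000", "1000-1500", ">1500"),
                    c(-Inf, 500, 1000, 1500, Inf)),
      c("<500" = 0.06, "500-1000" = 0.11, "1000-1500" = 0.29,
        ">1500" = 0.54),
      c(4, 4.009, 0.003, 0.9, 0.003), W["rainfall"]),
    temperature = .scheme("temperature", "degC", "interval",
      .intervalBins(c("<26", "26-29"), c(-Inf, 26, 29)),
      c("<26" = 0.25, "26-29" = 0.75),
      c(2, 2.000, 0.00, 0, 0.00), W["temperature"]))
}

#' Retrieve the packaged scheme set for a crop
#'
#' @param crop "rice" or "coconut".
#' @return named list of [ClassificationScheme-class].
#' @export
cropScheme <- function(crop = c("rice", "coconut")) {
  crop <- match.arg(crop)
  if (crop == "rice") riceScheme() else coconutScheme()
}

#' Serialize a classification scheme to YAML
#'
#' @param scheme a [ClassificationScheme-class] (or a named list of them).
#' @param path output file.
#' @export
writeScheme <- function(scheme, path) {
  one <- function(s) list(
    criterion = s@criterion, units = s@units, kind = s@kind,
    bins = s@bins, weights = as.list(s@weights),
    footer = as.list(s@footer), criterion_weight = s@criterionWeight)
  out <- if (is(scheme, "ClassificationScheme")) one(scheme)
         else lapply(scheme, one)
  yaml::write_yaml(out, path)
  invisible(path)
}

setMethod("show", "ClassificationScheme", function(object) {
  cat(sprintf("ClassificationScheme '%s' (%s, %s), criterion weight %.4f\n",
              object@criterion, object@units, object@kind,
              object@criterionWeight))
  for (lab in names(object@weights)) {
    if (object@kind == "interval") {
      b <- object@bins[object@bins$label == lab, , drop = FALSE]
      span <- paste(sprintf("[%g, %g)", b$lower, b$upper), collapse = " u ")
    } else {
      span <- paste(object@bins$category[object@bins$label == lab],
                    collapse = ", ")
    }
    cat(sprintf("  %-20s %.2f  %s\n", lab, object@weights[lab], span))
  }
  f <- object@footer
  cat(sprintf("  footer: n=%d lambda_max=%.3f CI=%.3f RI=%.2f CR=%.3f\n",
              as.integer(f["n"]), f["lambda_max"], f["ci"], f["ri"], f["cr"]))
})
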