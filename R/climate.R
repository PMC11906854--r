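## Climate layer derivation: monthly climatology, seasonal/annual aggregates
## and IDW downscaling with cross-validated power selection.

#' Build a monthly stack
#'
#' @param grids list of 12 co-registered [RasterGrid-class], Jan..Dec.
#' @param variable variable name, e.g. "temperature".
#' @param units "degC" or "mm".
#' @return A [MonthlyStack-class].
#' @export
monthlyStack <- function(grids, variable = "", units = "") {
  if (length(grids) != 12L)
    stop(sprintf("12 monthly grids required, got %d", length(grids)))
  new("MonthlyStack", grids = grids, variable = variable, units = units)
}

#' @rdname monthlyStack
#' @param x a [MonthlyStack-class].
#' @param month month index 1..12.
#' @export
monthGrid <- function(x, month) x@grids[[month]]

setMethod("show", "MonthlyStack", function(object) {
  g <- object@grids[[1]]
  cat(sprintf("MonthlyStack '%s' (%s), 12 x [%d x %d] grids\n",
              object@variable, object@units,
              nrow(g@values), ncol(g@values)))
})

#' Monthly climatology across years
#'
#' Cell-wise mean of each calendar month across all years.
#'
#' @param years list of per-year [MonthlyStack-class] objects (>= 1 year).
#' @return A [MonthlyStack-class] of 12 climatological means.
#' @export
climatology <- function(years) {
  if (length(years) < 1L) stop("at least one year required")
  stopifnot(all(vapply(years, is, logical(1), "MonthlyStack")))
  g1 <- years[[1]]@grids[[1]]
  for (y in years) for (m in 1:12) .stopIfMisaligned(y@grids[[m]], g1)
  grids <- lapply(1:12, function(m) {
    acc <- Reduce(`+`, lapply(years, function(y) y@grids[[m]]@values))
    rasterGrid(acc / length(years), g1@xll, g1@yll, g1@cellsize, g1@units)
  })
  monthlyStack(grids, years[[1]]@variable, years[[1]]@units)
}

#' Seasonal mean of a monthly stack
#'
#' Cell-wise mean over the listed months; the annual mean is the mean over
#' all 12 (used for the coconut temperature criterion, while rice uses the
#' June-September growing season).
#'
#' @param stack a [MonthlyStack-class].
#' @param months integer month subset of 1..12 (non-empty).
#' @return A [RasterGrid-class].
#' @examples
#' \dontrun{seasonMean(tstack, 6:9)  # rice growing-season mean}
#' @export
seasonMean <- function(stack, months = 1:12) {
  months <- as.integer(months)
  if (length(months) == 0L) stop("month set must be non-empty")
  if (!all(months %in% 1:12)) stop("months must lie in 1..12")
  g1 <- stack@grids[[1]]
  acc <- Reduce(`+`, lapply(stack@grids[months], slot, "values"))
  rasterGrid(acc / length(months), g1@xll, g1@yll, g1@cellsize, g1@units)
}

#' Annual precipitation total
#'
#' Cell-wise sum of the 12 monthly climatological precipitation grids (mm).
#' A missing month at a cell makes the annual total missing there.
#'
#' @param stack a precipitation [MonthlyStack-class].
#' @return A [RasterGrid-class] in mm.
#' @export
annualPrecip <- function(stack) {
  g1 <- stack@grids[[1]]
  acc <- Reduce(`+`, lapply(stack@grids, slot, "values"))
  rasterGrid(acc, g1@xll, g1@yll, g1@cellsize, units = "mm")
}

#' Inverse-distance-weighted interpolation onto a grid
#'
#' Predicts every cell of the template grid as the convex combination of the
#' `k` nearest sample values with weights d^(-power). A cell whose center
#' coincides with a sample location returns that sample's value exactly
#' (zero-distance short circuit).
#'
#' @param samples data.frame with columns x, y, value (map units); unique
#'   coordinates, finite values.
#' @param template grid supplying the output geometry.
#' @param power IDW power (> 0).
#' @param k number of nearest samples used per cell; `Inf` (or "all") uses
#'   every sample. Default 12.
#' @return A [RasterGrid-class] on the template geometry.
#' @export
idw <- function(samples, template, power = 2, k = 12) {
  .checkSamples(samples, 1L)
  if (identical(k, "all")) k <- Inf
  if (power <= 0) stop("power must be positive")
  v <- gridValues(template)
  ctr <- cellCenters(template)
  pred <- .idwPredict(samples$x, samples$y, samples$value,
                      ctr$x, ctr$y, power, k)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[cbind(ctr$row, ctr$col)] <- pred
  rasterGrid(out, template@xll, template@yll, template@cellsize)
}

# core predictor: targets (tx, ty) from samples (sx, sy, sv)
.idwPredict <- function(sx, sy, sv, tx, ty, power, k) {
  ns <- length(sx)
  kk <- min(k, ns)
  vapply(seq_along(tx), function(i) {
    d2 <- (sx - tx[i])^2 + (sy - ty[i])^2
    hit <- which(d2 < 1e-18)
    if (length(hit) > 0L) return(sv[hit[1]])
    use <- if (kk < ns) order(d2)[seq_len(kk)] else seq_len(ns)
    w <- d2[use]^(-power / 2)
    sum(w * sv[use]) / sum(w)
  }, numeric(1))
}

.checkSamples <- function(samples, minN) {
  if (!all(c("x", "y", "value") %in% names(samples)))
    stop("samples need columns x, y, value")
  if (nrow(samples) < minN)
    stop(sprintf("at least %d sample(s) required", minN))
  if (anyDuplicated(samples[, c("x", "y")]))
    stop("duplicate sample coordinates")
  if (!all(is.finite(samples$value))) stop("sample values must be finite")
  invisible(TRUE)
}

#' Select the IDW power by leave-one-out cross-validation
#'
#' Minimizes the leave-one-out RMSE of IDW predictions at the sample
#' locations over a bounded power interval, using one-dimensional bounded
#' minimization ([stats::optimize()]). The objective is evaluated with the
#' same IDW predictor used by [idw()].
#'
#' @param samples data.frame (x, y, value), >= 3 rows.
#' @param bounds numeric length-2 search interval, 0 < low < high.
#' @param k IDW neighborhood passed through to the predictor.
#' @return list with `power` (optimal power) and `rmse` (its leave-one-out
#'   RMSE).
#' @export
optimizePower <- function(samples, bounds = c(0.5, 20), k = 12) {
  .checkSamples(samples, 3L)
  if (length(bounds) != 2L || bounds[1] <= 0 || bounds[2] <= bounds[1])
    stop("bounds must satisfy 0 < low < high")
  if (stats::sd(samples$x) == 0 && stats::sd(samples$y) == 0)
    stop("degenerate samples: all locations identical")
  obj <- function(p) looRmse(samples, p, k)
  opt <- stats::optimize(obj, interval = bounds)
  list(power = opt$minimum, rmse = opt$objective)
}

#' @rdname optimizePower
#' @param power IDW power at which to evaluate the leave-one-out RMSE.
#' @export
looRmse <- function(samples, power, k = 12) {
  n <- nrow(samples)
  err <- vapply(seq_len(n), function(i) {
    pred <- .idwPredict(samples$x[-i], samples$y[-i], samples$value[-i],
                        samples$x[i], samples$y[i], power, k)
    pred - samples$value[i]
  }, numeric(1))
  sqrt(mean(err^2))
}
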