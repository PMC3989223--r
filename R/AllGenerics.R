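#' @include AllClasses.R
NULL

#' Grid accessors
#'
#' @param x a [GridSpec-class] or an object carrying one.
#' @return `gridOf()` the grid; `nCells()` the cell count; `cellCenters()` a
#'   data.frame with `cell` (row-major index from the lower-left), `x`, `y`.
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))

#' @rdname gridOf
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname gridOf
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' Semivariogram curve evaluation
#'
#' Evaluates the fitted family's closed form at lags `h`. At `h == 0` the
#' classical semivariance 0 is returned; for any `h > 0` the curve starts at
#' the nugget (the nugget is the right-limit at zero lag).
#'
#' @param model a [VariogramModel-class].
#' @param h numeric vector of lags, km.
#' @return semivariances, per-mil squared.
#' @export
setGeneric("gammaValue", function(model, h) standardGeneric("gammaValue"))

#' Variance-covariance accessors
#'
#' @param x a [CovStructure-class].
#' @return `covMatrix()` the 2x2 covariance matrix (rows/cols d2H, d34S).
#' @export
setGeneric("covMatrix", function(x) standardGeneric("covMatrix"))

setMethod("gridOf", "GridSpec", function(x) x)
setMethod("gridOf", "Isoscape", function(x) x@grid)
setMethod("gridOf", "LikelihoodSurface", function(x) x@grid)
setMethod("gridOf", "BinarySurface", function(x) x@grid)
setMethod("gridOf", "TrueField", function(x) x@grid)

setMethod("covMatrix", "CovStructure", function(x) {
  cv <- x@sigmaH * x@sigmaS * x@omega
  matrix(c(x@sigmaH^2, cv, cv, x@sigmaS^2), 2, 2,
         dimnames = list(c("d2H", "d34S"), c("d2H", "d34S")))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g km, origin (%g, %g) km\n",
              object@nx, object@ny, object@cell, object@xmin, object@ymin))
})

setMethod("show", "VariogramModel", function(object) {
  cat(sprintf(
    "VariogramModel(%s): nugget %.4g, partial sill %.4g (total sill %.4g), range %.4g km\n",
    object@family, object@nugget, object@psill,
    object@nugget + object@psill, object@range))
})

setMethod("show", "EmpiricalVariogram", function(object) {
  cat(sprintf("EmpiricalVariogram: %d bins up to %.1f km (%d pairs)\n",
              length(object@lag), object@maxLag, sum(object@np)))
})

setMethod("show", "Isoscape", function(object) {
  cat(sprintf("Isoscape '%s' on a %d x %d grid (%g km cells)\n",
              object@isotope, object@grid@nx, object@grid@ny,
              object@grid@cell))
  cat(sprintf("  predicted mean range: [%.1f, %.1f] per mil\n",
              min(object@mean), max(object@mean)))
  cat("  model: "); show(object@model)
  if (is.finite(object@rmse))
    cat(sprintf("  LOOCV RMSE: %.3g per mil\n", object@rmse))
})

setMethod("show", "CovStructure", function(object) {
  cat(sprintf(
    "CovStructure: sigma_H %.3g, sigma_S %.3g per mil, omega %.3g (n = %d)\n",
    object@sigmaH, object@sigmaS, object@omega, object@n))
})

setMethod("show", "LikelihoodSurface", function(object) {
  cat(sprintf("LikelihoodSurface '%s': %d cells, max cell mass %.3g\n",
              object@id, length(object@mass), max(object@mass)))
})

setMethod("show", "BinarySurface", function(object) {
  cat(sprintf(
    "BinarySurface '%s' (%g:1): %d of %d cells included, mass %.4f\n",
    object@id, object@odds, sum(object@included), length(object@included),
    object@includedMass))
})

setMethod("show", "SimConfig", function(object) {
  e <- object@extent
  cat(sprintf("SimConfig: %g x %g km, %d locations, seed %d\n",
              e[["xmax"]] - e[["xmin"]], e[["ymax"]] - e[["ymin"]],
              object@nLocations, object@seed))
})

setMethod("show", "TrueField", function(object) {
  cat(sprintf("TrueField '%s': intercept %g, gradient (%g, %g) per mil/km%s\n",
              object@isotope, object@intercept, object@gradient[1],
              object@gradient[2],
              if (any(object@smooth != 0)) ", with smooth component" else ""))
})
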