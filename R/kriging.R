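#' @include variogram.R
NULL

# the kriging equations use the same convention as gammaValue(): exact-zero
# lag contributes semivariance 0 (classical exact ordinary kriging), any
# positive lag starts at the nugget
krigingGamma <- function(model, h) gammaValue(model, h)

# Ordinary kriging of values z observed at (x, y) onto points (px, py).
# Returns list(pred, var, weights) where weights is n_obs x n_pred.
okSolve <- function(x, y, z, model, px, py) {
  n <- length(x)
  if (n < 2) stop("ordinary kriging needs >= 2 observations")
  d <- as.matrix(stats::dist(cbind(x, y)))
  dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup))
    stop(sprintf("singular kriging system: locations %d and %d share identical coordinates",
                 dup[1, 1], dup[1, 2]))
  if (model@nugget + model@psill == 0) {
    # zero-variance limit: any convex weighting is optimal; the classical
    # limit is the plain mean with zero kriging variance
    m <- length(px)
    return(list(pred = rep(mean(z), m), var = rep(0, m),
                weights = matrix(1 / n, n, m)))
  }
  A <- rbind(cbind(krigingGamma(model, d), 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(x, px, "-")^2 + outer(y, py, "-")^2)
  B <- rbind(krigingGamma(model, d0), 1)
  sol <- tryCatch(solve(A, B), error = function(e)
    stop("singular kriging system: ", conditionMessage(e)))
  wt <- sol[seq_len(n), , drop = FALSE]
  dimnames(wt) <- NULL
  mu <- unname(sol[n + 1, ])
  pred <- as.numeric(crossprod(wt, z))
  v <- colSums(wt * B[seq_len(n), , drop = FALSE]) + mu
  list(pred = pred, var = pmax(v, 0), weights = wt)
}

#' Ordinary kriging onto a grid
#'
#' Best linear unbiased prediction at every cell center of `grid` from the
#' location means, with weights constrained to sum to 1 and derived from the
#' fitted semivariogram. With a zero nugget the surface interpolates the data
#' exactly at the observation centroids.
#'
#' @param summaries location summaries ([summarizeLocations()]) or a
#'   data.frame with `x`, `y` and a value column.
#' @param model a fitted [VariogramModel-class].
#' @param grid a [GridSpec-class] covering all centroids.
#' @param value value column name (default `"mean"`).
#' @param isotope label stored on the result (default the value column).
#' @param rmse optional LOOCV RMSE to record as provenance.
#' @return an [Isoscape-class].
#' @export
krige <- function(summaries, model, grid, value = "mean",
                  isotope = value, rmse = NA_real_) {
  stopifnot(is(model, "VariogramModel"), is(grid, "GridSpec"))
  cc <- cellCenters(grid)
  sol <- okSolve(summaries$x, summaries$y, summaries[[value]], model,
                 cc$x, cc$y)
  new("Isoscape", isotope = isotope, grid = grid,
      mean = gridMat(sol$pred, grid), variance = gridMat(sol$var, grid),
      model = model, rmse = as.numeric(rmse))
}

#' Leave-one-out cross-validated RMSE of a variogram model
#'
#' For each location in turn, predicts its mean by ordinary kriging from all
#' other locations under `model` and accumulates the squared prediction
#' error; returns the root mean of those squares.
#'
#' @inheritParams krige
#' @return RMSE in per mil.
#' @export
loocvRMSE <- function(summaries, model, value = "mean") {
  n <- nrow(summaries)
  if (n < 4) stop("LOOCV needs >= 4 locations")
  z <- summaries[[value]]
  err <- vapply(seq_len(n), function(i) {
    sol <- okSolve(summaries$x[-i], summaries$y[-i], z[-i], model,
                   summaries$x[i], summaries$y[i])
    sol$pred - z[i]
  }, numeric(1))
  sqrt(mean(err^2))
}

#' Select the semivariogram family minimizing cross-validated RMSE
#'
#' Fits each candidate family to the empirical semivariogram of the location
#' means and returns the fitted model with the smallest leave-one-out RMSE.
#' Exact ties are broken by the order of `families` (default: the
#' conventional spherical, circular, exponential, gaussian, linear order).
#'
#' @inheritParams krige
#' @param families candidate family names, in tie-break order.
#' @param ... passed to [empiricalVariogram()].
#' @return the winning [VariogramModel-class], with attributes `rmse` (its
#'   LOOCV RMSE) and `rmseTable` (per-family RMSEs, `NA` where a fit failed).
#' @export
selectModel <- function(summaries, families = VARIOGRAM_FAMILIES,
                        value = "mean", ...) {
  ev <- empiricalVariogram(summaries, value = value, ...)
  fits <- vector("list", length(families))
  rmses <- rep(NA_real_, length(families))
  fails <- character()
  for (i in seq_along(families)) {
    res <- tryCatch({
      m <- fitVariogram(ev, families[i])
      list(model = m, rmse = loocvRMSE(summaries, m, value = value))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails <- c(fails, sprintf("%s: %s", families[i], conditionMessage(res)))
    } else {
      fits[[i]] <- res$model
      rmses[i] <- res$rmse
    }
  }
  if (all(is.na(rmses)))
    stop("no semivariogram family could be fitted:\n  ",
         paste(fails, collapse = "\n  "))
  best <- which.min(rmses)   # which.min takes the first of tied minima
  model <- fits[[best]]
  attr(model, "rmse") <- rmses[best]
  attr(model, "rmseTable") <- stats::setNames(rmses, families)
  model
}
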