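#' @include grid.R
NULL

#' Construct a semivariogram model
#'
#' @param family one of `"spherical"`, `"circular"`, `"exponential"`,
#'   `"gaussian"`, `"linear"` (the order also defines the tie-break used by
#'   [selectModel()]).
#' @param nugget nugget variance, per-mil squared.
#' @param psill partial sill, per-mil squared.
#' @param range range in km (practical range for exponential / gaussian).
#' @return a [VariogramModel-class].
#' @examples
#' m <- variogramModel("spherical", nugget = 1, psill = 5, range = 80)
#' gammaValue(m, c(0, 40, 80, 200))
#' @export
variogramModel <- function(family, nugget, psill, range) {
  new("VariogramModel", family = match.arg(family, VARIOGRAM_FAMILIES),
      nugget = as.numeric(nugget), psill = as.numeric(psill),
      range = as.numeric(range))
}

# unit-sill structural part g(h; a), g(0) = 0, g -> 1 at/beyond the range
# (linear is unbounded: g = h / a)
structuralGamma <- function(family, h, a) {
  r <- h / a
  switch(family,
    spherical = ifelse(r >= 1, 1, 1.5 * r - 0.5 * r^3),
    circular = ifelse(r >= 1, 1, {
      rc <- pmin(r, 1)
      1 - (2 / pi) * (acos(rc) - rc * sqrt(pmax(1 - rc^2, 0)))
    }),
    exponential = 1 - exp(-3 * r),
    gaussian = 1 - exp(-3 * r^2),
    linear = r,
    stop("unknown family '", family, "'"))
}

#' @rdname gammaValue
#' @export
setMethod("gammaValue", "VariogramModel", function(model, h) {
  g <- model@nugget + model@psill * structuralGamma(model@family, h, model@range)
  g[h == 0] <- 0
  g
})

#' Empirical semivariogram of location means
#'
#' Classical Matheron estimator over lag bins: for each bin, half the mean
#' squared difference of the location means over all pairs whose separation
#' falls in the bin. Bins retaining fewer than `minPairs` pairs are dropped.
#'
#' @param summaries location summaries as returned by [summarizeLocations()],
#'   or any data.frame with columns `x`, `y` and the value column.
#' @param value name of the value column (default `"mean"`).
#' @param nBins number of equal-width lag bins (default 12).
#' @param maxLag largest lag considered; defaults to half the maximum
#'   pairwise distance.
#' @param minPairs minimum pair count for a bin to be retained (default 3).
#' @return an [EmpiricalVariogram-class].
#' @export
empiricalVariogram <- function(summaries, value = "mean", nBins = 12,
                               maxLag = NULL, minPairs = 3) {
  stopifnot(all(c("x", "y", value) %in% names(summaries)))
  n <- nrow(summaries)
  if (n < 2) stop("need >= 2 locations to estimate a semivariogram")
  d <- as.matrix(stats::dist(summaries[, c("x", "y")]))
  z <- summaries[[value]]
  ut <- upper.tri(d)
  h <- d[ut]
  dz2 <- outer(z, z, "-")[ut]^2
  if (is.null(maxLag)) maxLag <- max(h) / 2
  keep <- h <= maxLag & h > 0
  if (!any(keep)) stop("all location pairs lie beyond maxLag = ", maxLag)
  h <- h[keep]; dz2 <- dz2[keep]
  breaks <- seq(0, maxLag, length.out = nBins + 1)
  bin <- cut(h, breaks, include.lowest = TRUE, labels = FALSE)
  gamma <- 0.5 * tapply(dz2, bin, mean)
  np <- tapply(dz2, bin, length)
  lag <- tapply(h, bin, mean)
  ok <- np >= minPairs
  if (sum(ok) < 1) stop("no lag bin retains >= ", minPairs, " pairs")
  new("EmpiricalVariogram", lag = as.numeric(lag[ok]),
      gamma = as.numeric(gamma[ok]), np = as.integer(np[ok]),
      maxLag = as.numeric(maxLag))
}

# Nonnegative weighted least squares for the two linear parameters
# (nugget c0, partial sill c) at a fixed range; returns list(c0, c, sse).
profileFit <- function(g, gamma, w) {
  fitClamped <- function(X) {
    XtW <- t(X * w)
    beta <- tryCatch(solve(XtW %*% X, XtW %*% gamma),
                     error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    as.numeric(beta)
  }
  X <- cbind(1, g)
  beta <- fitClamped(X)
  if (is.null(beta) || beta[1] < 0 || beta[2] < 0) {
    # clamp each parameter at 0 in turn, keep the better feasible fit
    cands <- list()
    num <- sum(w * g * gamma); den <- sum(w * g^2)
    cands[[1]] <- c(0, if (den > 0) max(num / den, 0) else 0)
    cands[[2]] <- c(max(sum(w * gamma) / sum(w), 0), 0)
    if (!is.null(beta)) beta <- NULL
    sses <- vapply(cands, function(b)
      sum(w * (gamma - b[1] - b[2] * g)^2), numeric(1))
    beta <- cands[[which.min(sses)]]
  }
  list(c0 = beta[1], c = beta[2],
       sse = sum(w * (gamma - beta[1] - beta[2] * g)^2))
}

#' Fit a semivariogram model family to an empirical semivariogram
#'
#' Weighted least squares with Cressie-style weights (pair count divided by
#' squared lag). For a fixed range the spherical, circular, exponential and
#' gaussian families are linear in nugget and partial sill, so those two are
#' profiled out in closed form (clamped at zero) and the range is found by a
#' fine golden-section search; the linear family reduces to a straight
#' weighted regression.
#'
#' @param ev an [EmpiricalVariogram-class] with >= 3 usable bins.
#' @param family model family name.
#' @return a fitted [VariogramModel-class].
#' @export
fitVariogram <- function(ev, family) {
  family <- match.arg(family, VARIOGRAM_FAMILIES)
  lag <- ev@lag; gamma <- ev@gamma
  if (length(lag) < 3) stop("need >= 3 usable bins to fit '", family, "'")
  w <- ev@np / lag^2
  if (all(gamma == 0))
    return(variogramModel(family, 0, 0, max(lag)))
  if (family == "linear") {
    href <- max(lag)
    fit <- profileFit(lag / href, gamma, w)
    return(variogramModel("linear", fit$c0, fit$c, href))
  }
  sseAt <- function(a) profileFit(structuralGamma(family, lag, a), gamma, w)$sse
  lo <- min(lag) / 10
  hi <- 3 * max(lag)
  # coarse grid guards against local minima, then golden-section polish
  grid <- exp(seq(log(lo), log(hi), length.out = 60))
  sses <- vapply(grid, sseAt, numeric(1))
  i <- which.min(sses)
  bracket <- c(grid[max(i - 1, 1)], grid[min(i + 1, length(grid))])
  opt <- stats::optimize(sseAt, interval = bracket, tol = 1e-10)
  # second polish pass tightens the range to ~1e-8 relative
  opt <- stats::optimize(sseAt,
                         interval = c(opt$minimum * 0.999, opt$minimum * 1.001),
                         tol = 1e-12)
  a <- opt$minimum
  fit <- profileFit(structuralGamma(family, lag, a), gamma, w)
  if (!all(is.finite(c(fit$c0, fit$c, a))))
    stop("variogram fit for family '", family, "' failed to converge (last ",
         "iterate: nugget ", fit$c0, ", psill ", fit$c, ", range ", a, ")")
  variogramModel(family, fit$c0, fit$c, a)
}
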