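#' @include calibration.R
NULL

#' Construct a within-location dispersion structure
#'
#' @param sigmaH,sigmaS residual SDs, per mil.
#' @param omega residual correlation, strictly inside (-1, 1).
#' @param n residual degrees of freedom behind the estimate (informational).
#' @return a [CovStructure-class].
#' @export
covStructure <- function(sigmaH, sigmaS, omega, n = 0L) {
  new("CovStructure", sigmaH = as.numeric(sigmaH), sigmaS = as.numeric(sigmaS),
      omega = as.numeric(omega), n = as.integer(n))
}

#' Estimate the within-location variance-covariance structure
#'
#' Pools residuals (individual value minus its location mean) across all
#' locations contributing at least two birds with both isotope values, and
#' estimates the two residual SDs and their correlation with
#' `N - L` degrees of freedom (`N` birds over `L` locations), i.e. the
#' pooled within-location (co)variance. Spatial stationarity of this
#' structure is assumed across the study area.
#'
#' @param records validation records with `loc_id`, `d2H`, `d34S`.
#' @return a [CovStructure-class] with `n` = residual degrees of freedom.
#' @export
estimateCovStructure <- function(records) {
  stopifnot(all(c("loc_id", "d2H", "d34S") %in% names(records)))
  ok <- is.finite(records$d2H) & is.finite(records$d34S)
  r <- records[ok, , drop = FALSE]
  counts <- table(r$loc_id)
  keep <- r$loc_id %in% names(counts)[counts >= 2]
  r <- r[keep, , drop = FALSE]
  if (nrow(r) == 0)
    stop("no location contributes >= 2 birds with both isotopes")
  loc <- as.character(r$loc_id)
  resH <- r$d2H - stats::ave(r$d2H, loc)
  resS <- r$d34S - stats::ave(r$d34S, loc)
  dfRes <- nrow(r) - length(unique(loc))
  if (dfRes < 2) stop("too few residual degrees of freedom (", dfRes, ")")
  sH <- sqrt(sum(resH^2) / dfRes)
  sS <- sqrt(sum(resS^2) / dfRes)
  if (sH == 0 || sS == 0)
    stop("degenerate dispersion: residuals are identically zero for ",
         if (sH == 0) "d2H" else "d34S")
  om <- sum(resH * resS) / dfRes / (sH * sS)
  if (abs(om) >= 1 - 1e-9)
    stop("degenerate dispersion: residual correlation at the boundary (",
         signif(om, 3), ")")
  covStructure(sH, sS, om, n = dfRes)
}

#' Bivariate normal probability density
#'
#' Density of the bivariate normal at observed isotope values `(x, y)` given
#' cell means `(muH, muS)` and the within-location dispersion structure:
#' \deqn{f = \frac{1}{2\pi\sigma_H\sigma_S\sqrt{1-\omega^2}}
#'   \exp\!\left(-\frac{z_H^2 - 2\omega z_H z_S + z_S^2}
#'   {2(1-\omega^2)}\right)}
#' with \eqn{z = (\mathrm{value}-\mu)/\sigma}. All arguments vectorize.
#'
#' @param x,y observed delta-2H and delta-34S, per mil.
#' @param muH,muS cell means, per mil.
#' @param cov a [CovStructure-class].
#' @return density values.
#' @examples
#' bnpdf(0, 0, 0, 0, covStructure(1, 1, 0))  # 1 / (2 * pi)
#' @export
bnpdf <- function(x, y, muH, muS, cov) {
  stopifnot(is(cov, "CovStructure"))
  validObject(cov)
  zH <- (x - muH) / cov@sigmaH
  zS <- (y - muS) / cov@sigmaS
  om2 <- 1 - cov@omega^2
  exp(-(zH^2 - 2 * cov@omega * zH * zS + zS^2) / (2 * om2)) /
    (2 * pi * cov@sigmaH * cov@sigmaS * sqrt(om2))
}

#' Per-individual origin likelihood surface
#'
#' Evaluates [bnpdf()] at every grid cell using that cell's predicted means
#' from the two isoscapes, then normalizes so the cell masses sum to 1.
#' Individuals missing either isotope value cannot be assigned bivariately
#' and are rejected with an informative error (callers batch-processing
#' cohorts should filter first; see [runPipeline()]).
#'
#' @param individual one record (list or single-row data.frame) with `id`,
#'   `d2H`, `d34S` (already corrected).
#' @param isoH,isoS the delta-2H and delta-34S [Isoscape-class] objects,
#'   sharing grid registration.
#' @param cov a [CovStructure-class].
#' @return a [LikelihoodSurface-class].
#' @export
likelihoodSurface <- function(individual, isoH, isoS, cov) {
  if (!sameGrid(isoH@grid, isoS@grid))
    stop("isoscapes do not share grid registration")
  x <- as.numeric(individual[["d2H"]])
  y <- as.numeric(individual[["d34S"]])
  id <- as.character(individual[["id"]])
  if (!is.finite(x) || !is.finite(y))
    stop("individual '", id, "' is missing ",
         if (!is.finite(x)) "d2H" else "d34S",
         " and cannot be assigned bivariately")
  dens <- bnpdf(x, y, isoH@mean, isoS@mean, cov)
  total <- sum(dens)
  if (total == 0) {
    # far tail underflow: fall back to log-density normalization
    zH <- (x - isoH@mean) / cov@sigmaH
    zS <- (y - isoS@mean) / cov@sigmaS
    om2 <- 1 - cov@omega^2
    ld <- -(zH^2 - 2 * cov@omega * zH * zS + zS^2) / (2 * om2)
    dens <- exp(ld - max(ld))
    total <- sum(dens)
  }
  mass <- dens / total
  # guard against accumulated float error in the sum
  mass <- mass / sum(mass)
  new("LikelihoodSurface", id = id, grid = isoH@grid, mass = mass)
}

#' Odds-ratio binarization of a likelihood surface
#'
#' Highest-density-region cut: cells are ranked by normalized mass
#' (descending, ties broken by ascending row-major cell index for
#' determinism) and included until the cumulative mass first reaches
#' `odds / (odds + 1)` — 2/3 for the conventional 2:1 odds ratio ("upper
#' 67%" of cumulative probability), 4/5 for 4:1. A cell whose inclusion
#' lands the cumulative mass exactly on the threshold is included.
#'
#' @param ls a [LikelihoodSurface-class].
#' @param odds odds ratio (> 0), e.g. 2 or 4.
#' @return a [BinarySurface-class].
#' @export
oddsBinarize <- function(ls, odds = 2) {
  stopifnot(is(ls, "LikelihoodSurface"), odds > 0)
  thr <- odds / (odds + 1)
  v <- gridVec(ls@mass)
  ord <- order(-v, seq_along(v))
  cum <- cumsum(v[ord])
  k <- which(cum >= thr - 1e-12)[1]
  if (is.na(k)) k <- length(v)
  inc <- logical(length(v))
  inc[ord[seq_len(k)]] <- TRUE
  new("BinarySurface", id = ls@id, odds = as.numeric(odds), grid = ls@grid,
      included = gridMat(as.integer(inc), ls@grid),
      includedMass = cum[k])
}

#' Sum binary origin surfaces over a cohort
#'
#' Per-cell count of individuals whose likely-origin region covers the cell;
#' the population-level depiction of assigned origin.
#'
#' @param surfaces list of [BinarySurface-class] objects on a shared grid.
#' @return an [Isoscape-class]-free plain list with `grid` and integer
#'   matrix `counts`.
#' @export
sumBinarySurfaces <- function(surfaces) {
  stopifnot(length(surfaces) >= 1)
  g <- surfaces[[1]]@grid
  counts <- matrix(0L, g@ny, g@nx)
  for (s in surfaces) {
    if (!sameGrid(s@grid, g)) stop("binary surfaces on mismatched grids")
    counts <- counts + s@included
  }
  list(grid = g, counts = counts)
}
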