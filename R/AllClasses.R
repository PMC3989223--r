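#' @import methods
NULL

VARIOGRAM_FAMILIES <- c("spherical", "circular", "exponential", "gaussian", "linear")

#' Regular analysis grid
#'
#' Planar grid in projected kilometres. Cells are registered on their centers,
#' row-major from the lower-left origin: row 1 is the southernmost row,
#' column 1 the westernmost column, and value matrices are indexed
#' `[row, col]` = `[y, x]`.
#'
#' @slot xmin,ymin coordinates (km) of the lower-left corner of the grid.
#' @slot cell cell size in km (square cells).
#' @slot nx,ny number of columns / rows.
#' @export
setClass("GridSpec",
  representation(xmin = "numeric", ymin = "numeric", cell = "numeric",
                 nx = "integer", ny = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@cell) != 1L || !is.finite(object@cell) || object@cell <= 0)
      msg <- c(msg, "'cell' must be a single positive number")
    if (object@nx < 1L || object@ny < 1L)
      msg <- c(msg, "'nx' and 'ny' must be >= 1")
    if (!is.finite(object@xmin) || !is.finite(object@ymin))
      msg <- c(msg, "grid origin must be finite")
    if (length(msg)) msg else TRUE
  })

#' Semivariogram model
#'
#' One of the five classical isotropic families with nugget, partial sill and
#' range. For the `exponential` and `gaussian` families the `range` slot holds
#' the practical range (lag at which the curve reaches 95% of its sill). The
#' `linear` family is unbounded: its slope is `psill / range` and the stored
#' `range` is only a reference lag.
#'
#' @slot family one of `"spherical"`, `"circular"`, `"exponential"`,
#'   `"gaussian"`, `"linear"`.
#' @slot nugget nugget variance (per-mil squared), >= 0.
#' @slot psill partial sill (per-mil squared), >= 0; total sill = nugget + psill.
#' @slot range range parameter in km, > 0.
#' @export
setClass("VariogramModel",
  representation(family = "character", nugget = "numeric",
                 psill = "numeric", range = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@family %in% VARIOGRAM_FAMILIES))
      msg <- c(msg, sprintf("unknown family '%s'", object@family))
    if (object@nugget < 0) msg <- c(msg, "nugget must be >= 0")
    if (object@psill < 0) msg <- c(msg, "partial sill must be >= 0")
    if (!is.finite(object@range) || object@range <= 0)
      msg <- c(msg, "range must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Empirical (binned) semivariogram
#'
#' Classical Matheron estimator per lag bin: half the mean squared difference
#' of values over all point pairs falling in the bin.
#'
#' @slot lag bin centers (km).
#' @slot gamma semivariance per bin (per-mil squared).
#' @slot np number of point pairs per bin.
#' @slot maxLag largest lag considered (km).
#' @export
setClass("EmpiricalVariogram",
  representation(lag = "numeric", gamma = "numeric", np = "integer",
                 maxLag = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@lag)
    if (length(object@gamma) != n || length(object@np) != n)
      msg <- c(msg, "lag, gamma and np must have equal length")
    if (any(object@gamma < 0)) msg <- c(msg, "semivariance must be >= 0")
    if (any(object@np < 1L)) msg <- c(msg, "every retained bin needs >= 1 pair")
    if (length(msg)) msg else TRUE
  })

#' Kriged isoscape
#'
#' A regular grid of predicted mean isotope values (per mil) together with
#' ordinary-kriging variances and the provenance of the prediction (fitted
#' semivariogram model and its leave-one-out RMSE).
#'
#' @slot isotope isotope label, e.g. `"d2H"` or `"d34S"`.
#' @slot grid the [GridSpec-class] the surfaces live on.
#' @slot mean matrix (`ny` x `nx`) of predicted means, per mil.
#' @slot variance matrix of kriging variances, per mil squared.
#' @slot model the [VariogramModel-class] used.
#' @slot rmse leave-one-out cross-validation RMSE of the model (per mil);
#'   `NA` when not evaluated.
#' @export
setClass("Isoscape",
  representation(isotope = "character", grid = "GridSpec", mean = "matrix",
                 variance = "matrix", model = "VariogramModel",
                 rmse = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- c(object@grid@ny, object@grid@nx)
    if (!identical(dim(object@mean), as.integer(d)))
      msg <- c(msg, "mean matrix does not match grid dimensions")
    if (!identical(dim(object@variance), as.integer(d)))
      msg <- c(msg, "variance matrix does not match grid dimensions")
    if (any(!is.finite(object@mean)))
      msg <- c(msg, "predicted means must be finite everywhere")
    if (length(msg)) msg else TRUE
  })

#' Within-location dispersion structure
#'
#' The spatially stationary variance-covariance structure used by every
#' bivariate assignment: within-location residual standard deviations of the
#' two isotopes and their residual correlation.
#'
#' @slot sigmaH within-location SD of delta-2H residuals, per mil.
#' @slot sigmaS within-location SD of delta-34S residuals, per mil.
#' @slot omega residual correlation, strictly inside (-1, 1).
#' @slot n number of residual degrees of freedom behind the estimate
#'   (0 when constructed directly).
#' @export
setClass("CovStructure",
  representation(sigmaH = "numeric", sigmaS = "numeric", omega = "numeric",
                 n = "integer"),
  prototype(n = 0L),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@sigmaH) || object@sigmaH <= 0)
      msg <- c(msg, "sigmaH must be > 0")
    if (!is.finite(object@sigmaS) || object@sigmaS <= 0)
      msg <- c(msg, "sigmaS must be > 0")
    if (!is.finite(object@omega) || abs(object@omega) >= 1)
      msg <- c(msg, "omega must lie strictly inside (-1, 1)")
    if (length(msg)) msg else TRUE
  })

#' Normalized per-individual origin likelihood surface
#'
#' Bivariate normal likelihood of each grid cell being the individual's origin,
#' normalized so the cell masses sum to 1 over the grid.
#'
#' @slot id individual identifier.
#' @slot grid the shared [GridSpec-class].
#' @slot mass matrix of normalized per-cell probability masses.
#' @export
setClass("LikelihoodSurface",
  representation(id = "character", grid = "GridSpec", mass = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@mass),
                   as.integer(c(object@grid@ny, object@grid@nx))))
      msg <- c(msg, "mass matrix does not match grid dimensions")
    if (any(object@mass < 0)) msg <- c(msg, "masses must be >= 0")
    if (abs(sum(object@mass) - 1) > 1e-9)
      msg <- c(msg, "masses must sum to 1 within 1e-9")
    if (length(msg)) msg else TRUE
  })

#' Binary (likely / unlikely origin) surface
#'
#' Odds-ratio highest-density region of a [LikelihoodSurface-class]: cells are
#' flagged 1 while the cumulative normalized mass of the highest-mass cells is
#' below `odds / (odds + 1)`, and 0 beyond.
#'
#' @slot id individual identifier.
#' @slot odds odds ratio used (2 for 2:1, 4 for 4:1).
#' @slot grid the shared [GridSpec-class].
#' @slot included integer matrix of 0/1 flags.
#' @slot includedMass total normalized mass of the included cells.
#' @export
setClass("BinarySurface",
  representation(id = "character", odds = "numeric", grid = "GridSpec",
                 included = "matrix", includedMass = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@included),
                   as.integer(c(object@grid@ny, object@grid@nx))))
      msg <- c(msg, "included matrix does not match grid dimensions")
    if (!all(object@included %in% c(0L, 1L)))
      msg <- c(msg, "included must be 0/1")
    if (object@odds <= 0) msg <- c(msg, "odds must be > 0")
    thr <- object@odds / (object@odds + 1)
    if (object@includedMass < thr - 1e-9 || object@includedMass > 1 + 1e-9)
      msg <- c(msg, "included mass must lie in [odds/(odds+1), 1]")
    if (length(msg)) msg else TRUE
  })

#' Frozen true isotopic landscape (synthetic)
#'
#' Deterministic linear gradient plus an optional smooth spatially correlated
#' component realized once on a coarse grid and interpolated bilinearly, so
#' evaluating the field twice at the same coordinate always returns the same
#' value.
#'
#' @slot isotope isotope label.
#' @slot intercept field value (per mil) at the coordinate origin (0, 0)
#'   before the smooth component.
#' @slot gradient length-2 gradient (per mil per km) in x and y.
#' @slot grid coarse realization [GridSpec-class].
#' @slot smooth matrix holding the realized smooth component (all zero when
#'   the spatial sill is 0).
#' @export
setClass("TrueField",
  representation(isotope = "character", intercept = "numeric",
                 gradient = "numeric", grid = "GridSpec", smooth = "matrix"),
  validity = function(object) {
    if (length(object@gradient) != 2L) "gradient must have length 2" else TRUE
  })

#' Synthetic study configuration
#'
#' All knobs of the synthetic-data generator. Defaults reproduce the sampling
#' design and dispersion structure the analysis assumes: a 340 x 530 km study
#' extent, 26 sampling locations at least 25 km apart, 3-10 after-second-year
#' (ASY) birds per location, within-location SDs of 10.5 and 3.8 per mil with
#' correlation 0.29, year shifts in delta-2H of -21.1 (2011) and -11.9 (2012)
#' per mil relative to the 2010 benchmark, and a -6 per-mil age shift for
#' second-year (SY) birds.
#'
#' @slot extent named numeric (xmin, xmax, ymin, ymax), km.
#' @slot nLocations number of sampling locations (>= 3).
#' @slot birdsPerLocation single count or (min, max) range per location.
#' @slot gridCell analysis cell size, km.
#' @slot fieldCell realization cell size for the smooth field component, km.
#' @slot interceptH,interceptS field value at the coordinate origin, per mil.
#' @slot gradientH,gradientS linear gradient (per mil per km) in (x, y).
#' @slot spatialRange,spatialSill,nugget smooth-component covariance
#'   parameters (km, per-mil squared, per-mil squared).
#' @slot sigmaH,sigmaS,omega within-location dispersion structure.
#' @slot yearOffsets named per-year shift in delta-2H (per mil); the entry
#'   equal to 0 is the benchmark year.
#' @slot ageOffset shift (per mil) added to SY birds' delta-2H.
#' @slot minSeparation minimum distance between locations, km.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  representation(extent = "numeric", nLocations = "integer",
                 birdsPerLocation = "integer", gridCell = "numeric",
                 fieldCell = "numeric",
                 interceptH = "numeric", interceptS = "numeric",
                 gradientH = "numeric", gradientS = "numeric",
                 spatialRange = "numeric", spatialSill = "numeric",
                 nugget = "numeric",
                 sigmaH = "numeric", sigmaS = "numeric", omega = "numeric",
                 yearOffsets = "numeric", ageOffset = "numeric",
                 minSeparation = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    e <- object@extent
    if (length(e) != 4L || is.null(names(e)) ||
        !all(c("xmin", "xmax", "ymin", "ymax") %in% names(e)))
      msg <- c(msg, "extent must be named (xmin, xmax, ymin, ymax)")
    else if (e["xmax"] <= e["xmin"] || e["ymax"] <= e["ymin"])
      msg <- c(msg, "extent must be strictly positive in both dimensions")
    if (object@nLocations < 3L)
      msg <- c(msg, "need >= 3 locations (variogram fitting needs >= 3 lags)")
    if (object@sigmaH <= 0 || object@sigmaS <= 0)
      msg <- c(msg, "sigmaH and sigmaS must be > 0")
    if (abs(object@omega) >= 1)
      msg <- c(msg, "omega must lie strictly inside (-1, 1)")
    if (object@spatialRange <= 0)
      msg <- c(msg, "spatialRange must be > 0")
    if (object@spatialSill < 0 || object@nugget < 0)
      msg <- c(msg, "spatialSill and nugget must be >= 0")
    if (!any(object@yearOffsets == 0))
      msg <- c(msg, "yearOffsets must contain a benchmark year with offset 0")
    if (length(msg)) msg else TRUE
  })
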