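#' @include isoscape.R
NULL

# run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  expr
}

#' Configure the synthetic study
#'
#' Builds a [SimConfig-class] with defaults emulating the coastal study
#' design the analysis was developed for: a 340 x 530 km extent, 26 sampling
#' locations at least 25 km apart, 3-10 ASY birds per location,
#' within-location SDs 10.5 and 3.8 per mil with correlation 0.29, delta-2H
#' year shifts of -21.1 (2011) and -11.9 (2012) per mil relative to the 2010
#' benchmark, and a -6 per-mil shift for SY birds. The delta-2H field is
#' enriched toward the southeast and the delta-34S field toward the eastern
#' (coastal) edge.
#'
#' @param extent named numeric (xmin, xmax, ymin, ymax), km.
#' @param nLocations number of sampling locations.
#' @param birdsPerLocation count or (min, max) range of ASY birds per location.
#' @param gridCell analysis cell size, km.
#' @param fieldCell smooth-field realization cell size, km.
#' @param interceptH,interceptS field value (per mil) at the coordinate
#'   origin (0, 0).
#' @param gradientH,gradientS per-mil-per-km gradients in (x, y).
#' @param spatialRange,spatialSill,nugget smooth-component covariance.
#' @param sigmaH,sigmaS,omega within-location dispersion structure.
#' @param yearOffsets named per-year delta-2H shifts; the 0 entry marks the
#'   benchmark year.
#' @param ageOffset per-mil shift applied to SY birds' delta-2H.
#' @param minSeparation minimum distance between locations, km.
#' @param seed RNG seed.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 42)
#' cfg
#' @export
simConfig <- function(extent = c(xmin = 0, xmax = 340, ymin = 0, ymax = 530),
                      nLocations = 26, birdsPerLocation = c(3, 10),
                      gridCell = 2, fieldCell = 10,
                      interceptH = -80, interceptS = 5,
                      gradientH = c(0.055, -0.055),
                      gradientS = c(0.02, 0),
                      spatialRange = 120, spatialSill = 8, nugget = 0,
                      sigmaH = 10.5, sigmaS = 3.8, omega = 0.29,
                      yearOffsets = c("2010" = 0, "2011" = -21.1,
                                      "2012" = -11.9),
                      ageOffset = -6, minSeparation = 25, seed = 1L) {
  bp <- as.integer(birdsPerLocation)
  if (length(bp) == 1L) bp <- c(bp, bp)
  new("SimConfig", extent = extent, nLocations = as.integer(nLocations),
      birdsPerLocation = bp, gridCell = gridCell, fieldCell = fieldCell,
      interceptH = interceptH, interceptS = interceptS,
      gradientH = gradientH, gradientS = gradientS,
      spatialRange = spatialRange, spatialSill = spatialSill, nugget = nugget,
      sigmaH = sigmaH, sigmaS = sigmaS, omega = omega,
      yearOffsets = yearOffsets, ageOffset = ageOffset,
      minSeparation = minSeparation, seed = as.integer(seed))
}

#' Benchmark year of a configuration
#'
#' @param config a [SimConfig-class].
#' @return the year (integer) whose delta-2H offset is 0.
#' @export
benchmarkYear <- function(config) {
  as.integer(names(config@yearOffsets)[config@yearOffsets == 0][1])
}

#' Realize a frozen true isotopic landscape
#'
#' Deterministic linear gradient around the extent center plus (when
#' `spatialSill > 0`) a smooth Gaussian-process component with a gaussian
#' covariance of the configured range and sill, realized once on the coarse
#' field grid by Cholesky factorization and interpolated bilinearly
#' thereafter. The realization is fully determined by the configuration seed
#' and the isotope label, so repeated evaluation at the same coordinate
#' always returns the same value.
#'
#' @param config a [SimConfig-class].
#' @param isotope `"d2H"` or `"d34S"`.
#' @return a [TrueField-class].
#' @export
generateTrueField <- function(config, isotope = c("d2H", "d34S")) {
  isotope <- match.arg(isotope)
  validObject(config)
  e <- config@extent
  grid <- gridSpec(e[["xmin"]], e[["xmax"]], e[["ymin"]], e[["ymax"]],
                   cell = config@fieldCell)
  smooth <- matrix(0, grid@ny, grid@nx)
  if (config@spatialSill > 0 || config@nugget > 0) {
    cc <- cellCenters(grid)
    n <- nrow(cc)
    z <- withSeed(config@seed + match(isotope, c("d2H", "d34S")), {
      zz <- numeric(n)
      if (config@spatialSill > 0) {
        d <- as.matrix(stats::dist(cc[, c("x", "y")]))
        C <- config@spatialSill * exp(-3 * (d / config@spatialRange)^2)
        diag(C) <- diag(C) + 1e-8 * config@spatialSill
        zz <- zz + as.numeric(t(chol(C)) %*% stats::rnorm(n))
      }
      if (config@nugget > 0)
        zz <- zz + stats::rnorm(n, sd = sqrt(config@nugget))
      zz
    })
    smooth <- gridMat(z, grid)
  }
  new("TrueField", isotope = isotope,
      intercept = if (isotope == "d2H") config@interceptH else config@interceptS,
      gradient = if (isotope == "d2H") config@gradientH else config@gradientS,
      grid = grid, smooth = smooth)
}

#' Evaluate a true field
#'
#' @param field a [TrueField-class].
#' @param x,y coordinates, km.
#' @return mean isotope values, per mil.
#' @export
fieldValue <- function(field, x, y) {
  g <- field@grid
  v <- field@intercept + field@gradient[1] * x + field@gradient[2] * y
  if (any(field@smooth != 0))
    v <- v + bilinearInterp(g, field@smooth, x, y)
  v
}

#' Place sampling locations
#'
#' Seeded uniform sampling over the extent with a minimum-separation
#' constraint, mimicking a spatially spread survey design and preventing
#' degenerate (near-zero) variogram lags.
#'
#' @param config a [SimConfig-class].
#' @return data.frame `loc_id`, `x`, `y`.
#' @export
placeLocations <- function(config) {
  e <- config@extent
  withSeed(config@seed, {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0
    while (length(xs) < config@nLocations) {
      x <- stats::runif(1, e[["xmin"]], e[["xmax"]])
      y <- stats::runif(1, e[["ymin"]], e[["ymax"]])
      if (!length(xs) ||
          min(sqrt((xs - x)^2 + (ys - y)^2)) >= config@minSeparation) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
      tries <- tries + 1
      if (tries > 10000 * config@nLocations)
        stop("cannot place ", config@nLocations,
             " locations with minimum separation ", config@minSeparation,
             " km in this extent")
    }
    data.frame(loc_id = sprintf("L%02d", seq_len(config@nLocations)),
               x = xs, y = ys, stringsAsFactors = FALSE)
  })
}

# default survey plan: every non-benchmark year is visited at 3 locations
# (taken from the end of the location list), the rest in the benchmark year
defaultYearPlan <- function(config, nLoc) {
  years <- as.integer(names(config@yearOffsets))
  plan <- rep(benchmarkYear(config), nLoc)
  others <- setdiff(years, benchmarkYear(config))
  k <- nLoc
  for (yr in rev(others)) {
    take <- min(3, k - 1)
    plan[seq(k - take + 1, k)] <- yr
    k <- k - take
  }
  plan
}

#' Simulate individual birds at the sampling locations
#'
#' Each bird's (delta-2H, delta-34S) pair is drawn from a bivariate normal
#' centred on the true-field values at its location, with covariance built
#' from `(sigmaH, sigmaS, omega)`. Birds captured in year `y` have the
#' configured year offset added to delta-2H; SY birds additionally receive
#' the age offset (delta-34S is never shifted). The true origin is stored
#' with each record for later scoring but is never used by the assignment
#' stage.
#'
#' @param config a [SimConfig-class].
#' @param fieldH,fieldS frozen [TrueField-class] objects (defaults generated
#'   from `config`).
#' @param locations data.frame `loc_id`, `x`, `y`; default [placeLocations()].
#' @param years per-location capture year; default: three locations per
#'   non-benchmark year, the rest in the benchmark year.
#' @param ages per-bird age class recycled per location (`"ASY"` default).
#' @return data.frame of records: `id`, `loc_id`, `x_km`, `y_km`, `year`,
#'   `age`, `d2H`, `d34S`, `true_x_km`, `true_y_km`.
#' @export
simulateIndividuals <- function(config,
                                fieldH = generateTrueField(config, "d2H"),
                                fieldS = generateTrueField(config, "d34S"),
                                locations = placeLocations(config),
                                years = NULL, ages = "ASY") {
  validObject(config)
  nLoc <- nrow(locations)
  if (is.null(years)) years <- defaultYearPlan(config, nLoc)
  years <- rep_len(years, nLoc)
  known <- as.integer(names(config@yearOffsets))
  if (!all(years %in% known))
    stop("year(s) not covered by yearOffsets: ",
         paste(setdiff(years, known), collapse = ", "))
  Sigma <- matrix(c(config@sigmaH^2,
                    config@sigmaH * config@sigmaS * config@omega,
                    config@sigmaH * config@sigmaS * config@omega,
                    config@sigmaS^2), 2, 2)
  withSeed(config@seed + 1000L, {
    rows <- vector("list", nLoc)
    for (i in seq_len(nLoc)) {
      nB <- if (config@birdsPerLocation[1] == config@birdsPerLocation[2])
        config@birdsPerLocation[1]
      else sample(config@birdsPerLocation[1]:config@birdsPerLocation[2], 1)
      muH <- fieldValue(fieldH, locations$x[i], locations$y[i])
      muS <- fieldValue(fieldS, locations$x[i], locations$y[i])
      iso <- MASS::mvrnorm(nB, mu = c(muH, muS), Sigma = Sigma)
      iso <- matrix(iso, ncol = 2)
      age <- rep_len(ages, nB)
      d2H <- iso[, 1] + config@yearOffsets[as.character(years[i])] +
        ifelse(age == "SY", config@ageOffset, 0)
      rows[[i]] <- data.frame(
        id = sprintf("%s_b%02d", locations$loc_id[i], seq_len(nB)),
        loc_id = locations$loc_id[i],
        x_km = locations$x[i], y_km = locations$y[i],
        year = years[i], age = age,
        d2H = unname(d2H), d34S = iso[, 2],
        true_x_km = locations$x[i], true_y_km = locations$y[i],
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate birds of known origin anywhere on the landscape
#'
#' Draws `n` birds at uniform random points of the extent with isotope values
#' from the bivariate within-location model around the local true-field
#' means, for scoring assignment coverage and classification accuracy against
#' a known origin.
#'
#' @inheritParams simulateIndividuals
#' @param n number of birds.
#' @param year capture year (default the benchmark year).
#' @param age age class (`"SY"` default; SY birds get the age offset).
#' @param seed RNG seed (default derived from the configuration).
#' @return record data.frame as in [simulateIndividuals()], with `true_x_km`,
#'   `true_y_km` the actual origin.
#' @export
simulateKnownOrigins <- function(config,
                                 fieldH = generateTrueField(config, "d2H"),
                                 fieldS = generateTrueField(config, "d34S"),
                                 n = 200, year = benchmarkYear(config),
                                 age = "SY", seed = config@seed + 2000L) {
  e <- config@extent
  if (!as.character(year) %in% names(config@yearOffsets))
    stop("year ", year, " not covered by yearOffsets")
  Sigma <- matrix(c(config@sigmaH^2,
                    config@sigmaH * config@sigmaS * config@omega,
                    config@sigmaH * config@sigmaS * config@omega,
                    config@sigmaS^2), 2, 2)
  withSeed(seed, {
    x <- stats::runif(n, e[["xmin"]], e[["xmax"]])
    y <- stats::runif(n, e[["ymin"]], e[["ymax"]])
    mu <- cbind(fieldValue(fieldH, x, y), fieldValue(fieldS, x, y))
    eps <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = Sigma)
    eps <- matrix(eps, ncol = 2)
    d2H <- mu[, 1] + eps[, 1] +
      config@yearOffsets[as.character(year)] +
      ifelse(age == "SY", config@ageOffset, 0)
    data.frame(id = sprintf("K%04d", seq_len(n)),
               loc_id = NA_character_, x_km = x, y_km = y,
               year = as.integer(year), age = age,
               d2H = unname(d2H), d34S = mu[, 2] + eps[, 2],
               true_x_km = x, true_y_km = y, stringsAsFactors = FALSE)
  })
}

#' Simulate a full dual-isotope survey
#'
#' Generates a complete study dataset mirroring the sampling design the
#' pipeline expects: a cluster of benchmark locations (the focal district of
#' known-origin birds) plus outlying sampling locations, after-second-year
#' (ASY) birds surveyed across years with sulfur measured only on a
#' subsample, returning ASY birds at the benchmark in every year (the year
#' calibration series), and a cohort of second-year (SY) recruits at the
#' benchmark. Default counts reproduce the design of the motivating survey:
#' 142 ASY over 22 outside locations (sulfur on 3 birds per location),
#' returning ASY of 23 / 14 / 11 in 2010 / 2011 / 2012 (sulfur missing in
#' 2011), and 35 SY birds — so the isoscape-eligible totals are 165 birds
#' for delta-2H and 89 for delta-34S.
#'
#' @param config a [SimConfig-class]; its dispersion, offsets and seed drive
#'   the generation.
#' @param nOutside number of outlying sampling locations.
#' @param outsideASY total ASY birds across the outside locations.
#' @param sulfurPerLocation outside birds per location with delta-34S.
#' @param outsideYears number of outside locations surveyed in each year
#'   (named; must sum to `nOutside`).
#' @param returningASY named per-year counts of returning ASY at the
#'   benchmark.
#' @param sulfurYears years in which returning ASY have delta-34S.
#' @param nSY SY cohort size at the benchmark (benchmark year).
#' @param nBenchmarkLocs number of pooled benchmark locations.
#' @return list with `records` (all birds), `benchmarkLocs` (their
#'   `loc_id`s) and `locations` (all location coordinates).
#' @export
simulateStudy <- function(config,
                          nOutside = 22, outsideASY = 142,
                          sulfurPerLocation = 3,
                          outsideYears = c("2010" = 16, "2011" = 3,
                                           "2012" = 3),
                          returningASY = c("2010" = 23, "2011" = 14,
                                           "2012" = 11),
                          sulfurYears = c(2010, 2012),
                          nSY = 35, nBenchmarkLocs = 4) {
  validObject(config)
  stopifnot(sum(outsideYears) == nOutside)
  e <- config@extent
  fieldH <- generateTrueField(config, "d2H")
  fieldS <- generateTrueField(config, "d34S")
  Sigma <- covMatrix(covStructure(config@sigmaH, config@sigmaS,
                                  config@omega))
  offsets <- config@yearOffsets
  benchYear <- benchmarkYear(config)

  # outside locations via the seeded placement; benchmark district as a
  # compact cluster (~80 x 25 km footprint) at the extent center
  outCfg <- config
  outCfg@nLocations <- as.integer(nOutside)
  outside <- placeLocations(outCfg)
  cx <- (e[["xmin"]] + e[["xmax"]]) / 2
  cy <- (e[["ymin"]] + e[["ymax"]]) / 2
  bench <- data.frame(
    loc_id = sprintf("BB%d", seq_len(nBenchmarkLocs)),
    x = cx + seq(-30, 30, length.out = nBenchmarkLocs),
    y = cy + rep(c(-6, 6), length.out = nBenchmarkLocs),
    stringsAsFactors = FALSE)

  # spread a total as evenly as integers allow
  splitTotal <- function(total, k) {
    base <- total %/% k
    n <- rep(base, k)
    if (total %% k > 0) n[seq_len(total %% k)] <- base + 1
    n
  }
  outCounts <- splitTotal(outsideASY, nOutside)
  outYear <- rep(as.integer(names(outsideYears)), times = outsideYears)

  draw <- function(locRow, n, year, age, sulfur, prefix) {
    mu <- c(fieldValue(fieldH, locRow$x, locRow$y),
            fieldValue(fieldS, locRow$x, locRow$y))
    iso <- matrix(MASS::mvrnorm(n, mu = mu, Sigma = Sigma), ncol = 2)
    d2H <- iso[, 1] + offsets[as.character(year)] +
      ifelse(age == "SY", config@ageOffset, 0)
    d34S <- iso[, 2]
    d34S[!sulfur] <- NA_real_
    data.frame(id = sprintf("%s_%s_%02d", prefix, locRow$loc_id, seq_len(n)),
               loc_id = locRow$loc_id, x_km = locRow$x, y_km = locRow$y,
               year = as.integer(year), age = age, d2H = unname(d2H),
               d34S = d34S, true_x_km = locRow$x, true_y_km = locRow$y,
               stringsAsFactors = FALSE)
  }

  withSeed(config@seed + 3000L, {
    rows <- list()
    for (i in seq_len(nOutside)) {
      n <- outCounts[i]
      sulfur <- seq_len(n) <= sulfurPerLocation
      rows[[length(rows) + 1L]] <-
        draw(outside[i, ], n, outYear[i], "ASY", sulfur, "OUT")
    }
    for (yr in names(returningASY)) {
      perLoc <- splitTotal(returningASY[[yr]], nBenchmarkLocs)
      for (j in seq_len(nBenchmarkLocs)) {
        if (perLoc[j] == 0) next
        rows[[length(rows) + 1L]] <-
          draw(bench[j, ], perLoc[j], yr, "ASY",
               rep(as.integer(yr) %in% sulfurYears, perLoc[j]),
               paste0("RET", yr))
      }
    }
    syPerLoc <- splitTotal(nSY, nBenchmarkLocs)
    for (j in seq_len(nBenchmarkLocs)) {
      if (syPerLoc[j] == 0) next
      rows[[length(rows) + 1L]] <-
        draw(bench[j, ], syPerLoc[j], benchYear, "SY",
             rep(TRUE, syPerLoc[j]), "SY")
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    list(records = records, benchmarkLocs = bench$loc_id,
         locations = rbind(outside, bench))
  })
}
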