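# shared fixtures, all generated in code

# summaries drawn from a Gaussian-process realization of a known variogram
# model: the reference data-generating process for the geostatistics tests
gpSummaries <- function(seed, family, nugget, sill, range, n = 40,
                        ext = 400) {
  set.seed(seed)
  x <- stats::runif(n, 0, ext)
  y <- stats::runif(n, 0, ext)
  m0 <- variogramModel(family, nugget, sill, range)
  D <- as.matrix(stats::dist(cbind(x, y)))
  C <- (nugget + sill) - gammaValue(m0, D)
  diag(C) <- nugget + sill + 1e-8
  z <- as.numeric(t(chol(C)) %*% stats::rnorm(n))
  data.frame(x = x, y = y, mean = z)
}

# noiseless empirical variogram evaluated exactly on a model curve
exactEV <- function(model, lags = seq(10, 200, length.out = 10)) {
  new("EmpiricalVariogram", lag = lags, gamma = gammaValue(model, lags),
      np = rep(10L, length(lags)), maxLag = max(lags))
}

# tiny likelihood surface with hand-set masses on an nx x 1 strip grid
massSurface <- function(masses, cell = 1, id = "toy") {
  g <- gridSpec(0, length(masses) * cell, 0, cell, cell = cell)
  new("LikelihoodSurface", id = id, grid = g,
      mass = matrix(masses / sum(masses), nrow = 1))
}

# true fields turned into exact Isoscape objects on an analysis grid:
# isolates assignment behavior from kriging error
fieldIsoscape <- function(field, grid, label) {
  cc <- cellCenters(grid)
  new("Isoscape", isotope = label, grid = grid,
      mean = matrix(fieldValue(field, cc$x, cc$y), grid@ny, grid@nx,
                    byrow = TRUE),
      variance = matrix(0, grid@ny, grid@nx),
      model = variogramModel("gaussian", 0, 1, 100), rmse = NA_real_)
}

# row-major vector view of a surface matrix (independent of package helpers)
rmVec <- function(m) as.vector(t(m))
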