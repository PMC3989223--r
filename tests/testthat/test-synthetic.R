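test_that("degenerate and linear true fields evaluate as plain arithmetic", {
  cfg <- simConfig(extent = c(xmin = 0, xmax = 800, ymin = 0, ymax = 100),
                   gradientH = c(0, 0), interceptH = -70, spatialSill = 0,
                   seed = 1)
  f <- generateTrueField(cfg, "d2H")
  set.seed(2)
  x <- runif(20, 0, 800); y <- runif(20, 0, 100)
  expect_equal(fieldValue(f, x, y), rep(-70, 20))

  cfg2 <- simConfig(extent = c(xmin = 0, xmax = 800, ymin = 0, ymax = 100),
                    gradientH = c(0.05, 0), interceptH = -90, spatialSill = 0,
                    seed = 1)
  f2 <- generateTrueField(cfg2, "d2H")
  expect_equal(fieldValue(f2, 400, 50), -70)
  # frozen field: identical evaluations
  expect_identical(fieldValue(f2, 123.4, 56.7), fieldValue(f2, 123.4, 56.7))
})

test_that("invalid spatial parameters are rejected", {
  expect_error(simConfig(spatialRange = -5), "spatialRange")
  expect_error(simConfig(spatialSill = -1), "spatialSill")
  expect_error(simConfig(nLocations = 2), ">= 3")
  expect_error(simConfig(omega = 1), "omega")
})

test_that("smooth component reaches the configured sill at long lags", {
  cfg <- simConfig(seed = 11, gradientH = c(0, 0), interceptH = 0,
                   spatialRange = 40, spatialSill = 8)
  f <- generateTrueField(cfg, "d2H")
  set.seed(1)
  x <- runif(2500, 0, 340); y <- runif(2500, 0, 530)
  v <- fieldValue(f, x, y)
  d <- as.matrix(dist(cbind(x, y)))
  ut <- upper.tri(d)
  dz2 <- outer(v, v, "-")[ut]^2
  h <- d[ut]
  sel <- h > 3 * cfg@spatialRange & h < 400
  # direct empirical semivariance of the realized surface vs configured sill
  semiv <- 0.5 * mean(dz2[sel])
  expect_lt(abs(semiv / cfg@spatialSill - 1), 0.20)
})

test_that("zero-noise limit returns field values plus offsets exactly", {
  cfg <- simConfig(seed = 4, sigmaH = 1e-9, sigmaS = 1e-9, omega = 0,
                   spatialSill = 0, nLocations = 5, birdsPerLocation = 2)
  fH <- generateTrueField(cfg, "d2H"); fS <- generateTrueField(cfg, "d34S")
  loc <- placeLocations(cfg)
  rec <- simulateIndividuals(cfg, fH, fS, locations = loc,
                             years = rep(2011, 5), ages = "SY")
  muH <- fieldValue(fH, rec$x_km, rec$y_km)
  muS <- fieldValue(fS, rec$x_km, rec$y_km)
  expect_equal(rec$d2H, muH - 21.1 - 6, tolerance = 1e-6)
  expect_equal(rec$d34S, muS, tolerance = 1e-6)
})

test_that("unknown years are rejected", {
  cfg <- simConfig(seed = 4, nLocations = 3, birdsPerLocation = 2)
  expect_error(simulateIndividuals(cfg, years = rep(1999, 3)),
               "not covered by yearOffsets")
  expect_error(simulateKnownOrigins(cfg, n = 2, year = 1999),
               "not covered")
})

test_that("within-location dispersion converges to the configured matrix", {
  one <- data.frame(loc_id = "L1", x = 150, y = 150)
  # omega = 0: sample correlation near zero
  cfg0 <- simConfig(seed = 8, omega = 0, nLocations = 3,
                    birdsPerLocation = 10000, spatialSill = 0)
  r0 <- simulateIndividuals(cfg0, locations = one)
  expect_lt(abs(cor(r0$d2H, r0$d34S)), 0.03)
  # defaults: pooled SDs within 2%, covariance matrix within 5%
  cfg1 <- simConfig(seed = 9, nLocations = 3, birdsPerLocation = 10000,
                    spatialSill = 0)
  r1 <- simulateIndividuals(cfg1, locations = one)
  expect_lt(abs(sd(r1$d2H) / 10.5 - 1), 0.02)
  expect_lt(abs(sd(r1$d34S) / 3.8 - 1), 0.02)
  emp <- cov(cbind(r1$d2H, r1$d34S))
  expected <- covMatrix(covStructure(10.5, 3.8, 0.29))
  expect_lt(max(abs(emp / expected - 1)), 0.05)
})

test_that("identical configurations reproduce byte-identical tables", {
  cfg <- simConfig(seed = 13, nLocations = 8, birdsPerLocation = c(3, 10))
  a <- simulateIndividuals(cfg)
  b <- simulateIndividuals(simConfig(seed = 13, nLocations = 8,
                                     birdsPerLocation = c(3, 10)))
  expect_identical(a, b)
  expect_identical(placeLocations(cfg), placeLocations(cfg))
  f1 <- generateTrueField(cfg, "d2H"); f2 <- generateTrueField(cfg, "d2H")
  expect_identical(f1@smooth, f2@smooth)
})

test_that("year and age offsets are pure translations of d2H", {
  base <- function(ageOffset, years) {
    cfg <- simConfig(seed = 21, nLocations = 4, birdsPerLocation = 5,
                     ageOffset = ageOffset, spatialSill = 0)
    simulateIndividuals(cfg, years = years, ages = "SY")
  }
  shifted <- base(-6, rep(2011, 4))
  plain <- base(0, rep(2010, 4))
  expect_equal(shifted$d2H - (-21.1) - (-6), plain$d2H)
  expect_equal(shifted$d34S, plain$d34S)
})

test_that("locations respect the minimum-separation constraint", {
  cfg <- simConfig(seed = 30)
  loc <- placeLocations(cfg)
  expect_equal(nrow(loc), 26L)
  expect_gte(min(dist(loc[, c("x", "y")])), 25)
})
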