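test_that("covariance structure is recovered from pooled residuals", {
  # small validation cohort: 22 locations x 3 birds (fixed seed; at this n
  # the correlation estimate carries an SE of ~0.14, hence the wide band)
  cfg <- simConfig(seed = 9, nLocations = 22, birdsPerLocation = 3,
                   spatialSill = 0)
  cs <- estimateCovStructure(simulateIndividuals(cfg))
  expect_lt(abs(cs@sigmaH / 10.5 - 1), 0.25)
  expect_lt(abs(cs@sigmaS / 3.8 - 1), 0.25)
  expect_lt(abs(cs@omega / 0.29 - 1), 0.25)
  expect_equal(cs@n, 66L - 22L)
})

test_that("degenerate residual structures are rejected", {
  rec <- data.frame(loc_id = rep(c("a", "b"), each = 3),
                    d2H = rep(c(-70, -80), each = 3),
                    d34S = rep(c(6, 7), each = 3))
  expect_error(estimateCovStructure(rec), "identically zero")
  # perfectly correlated residuals: omega at the boundary
  rec2 <- data.frame(loc_id = rep(c("a", "b"), each = 2),
                     d2H = c(-1, 1, -1, 1), d34S = c(-1, 1, -1, 1))
  expect_error(estimateCovStructure(rec2), "boundary")
  # all singletons
  rec3 <- data.frame(loc_id = c("a", "b", "c"), d2H = 1:3, d34S = 1:3)
  expect_error(estimateCovStructure(rec3), ">= 2 birds")
})

test_that("bnpdf matches the standard bivariate normal density", {
  # standard normal mode: 1 / (2 pi)
  expect_equal(bnpdf(0, 0, 0, 0, covStructure(1, 1, 0)), 1 / (2 * pi),
               tolerance = 1e-12)
  # independent oracle: generic multivariate normal density
  skip_if_not_installed("mvtnorm")
  cv <- covStructure(10.5, 3.8, 0.29)
  Sigma <- covMatrix(cv)
  expect_equal(bnpdf(-70, 7, -70, 7, cv),
               mvtnorm::dmvnorm(c(-70, 7), c(-70, 7), Sigma),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    xy <- rnorm(2, c(-70, 7), c(15, 5))
    expect_equal(bnpdf(xy[1], xy[2], -70, 7, cv),
                 mvtnorm::dmvnorm(xy, c(-70, 7), Sigma), tolerance = 1e-12)
  }
  # omega = 0 factorizes into the product of univariate densities
  cv0 <- covStructure(10.5, 3.8, 0)
  expect_equal(bnpdf(-65, 8, -70, 7, cv0),
               dnorm(-65, -70, 10.5) * dnorm(8, 7, 3.8), tolerance = 1e-12)
  expect_error(covStructure(1, 1, 1), "omega")
})

test_that("likelihood surfaces normalize and localize correctly", {
  g <- gridSpec(0, 30, 0, 20, cell = 10)
  flat <- new("Isoscape", isotope = "d2H", grid = g,
              mean = matrix(-70, 2, 3), variance = matrix(0, 2, 3),
              model = variogramModel("linear", 0, 1, 1), rmse = NA_real_)
  flatS <- new("Isoscape", isotope = "d34S", grid = g,
               mean = matrix(7, 2, 3), variance = matrix(0, 2, 3),
               model = variogramModel("linear", 0, 1, 1), rmse = NA_real_)
  cv <- covStructure(10.5, 3.8, 0.29)
  ls1 <- likelihoodSurface(list(id = "u", d2H = -64, d34S = 8), flat, flatS, cv)
  expect_equal(as.vector(ls1@mass), rep(1 / 6, 6))
  # mode at the cell whose means match the individual exactly
  grad <- flat
  grad@mean <- matrix(c(-90, -80, -70, -60, -50, -40), 2, 3, byrow = TRUE)
  gradS <- flatS
  gradS@mean <- matrix(c(4, 5, 6, 7, 8, 9), 2, 3, byrow = TRUE)
  ls2 <- likelihoodSurface(list(id = "v", d2H = -60, d34S = 7), grad, gradS, cv)
  expect_equal(which.max(rmVec(ls2@mass)), 4L)
  expect_equal(sum(ls2@mass), 1, tolerance = 1e-12)
  # grid mismatch and missing isotope
  g2 <- gridSpec(0, 30, 0, 20, cell = 5)
  other <- new("Isoscape", isotope = "d34S", grid = g2,
               mean = matrix(7, 4, 6), variance = matrix(0, 4, 6),
               model = variogramModel("linear", 0, 1, 1), rmse = NA_real_)
  expect_error(likelihoodSurface(list(id = "w", d2H = -60, d34S = 7),
                                 flat, other, cv), "registration")
  expect_error(likelihoodSurface(list(id = "x", d2H = -60, d34S = NA),
                                 flat, flatS, cv), "missing d34S")
})

test_that("three-cell toy surface matches a by-hand density evaluation", {
  g <- gridSpec(0, 3, 0, 1, cell = 1)
  isoH <- new("Isoscape", isotope = "d2H", grid = g,
              mean = matrix(c(-80, -70, -60), 1, 3),
              variance = matrix(0, 1, 3),
              model = variogramModel("linear", 0, 1, 1), rmse = NA_real_)
  isoS <- new("Isoscape", isotope = "d34S", grid = g,
              mean = matrix(c(5, 7, 9), 1, 3), variance = matrix(0, 1, 3),
              model = variogramModel("linear", 0, 1, 1), rmse = NA_real_)
  cv <- covStructure(10.5, 3.8, 0.29)
  x <- -72; y <- 6.5
  # hand evaluation of the closed-form density at each cell
  byHand <- vapply(1:3, function(j) {
    zH <- (x - isoH@mean[1, j]) / 10.5
    zS <- (y - isoS@mean[1, j]) / 3.8
    om <- 0.29
    exp(-(zH^2 - 2 * om * zH * zS + zS^2) / (2 * (1 - om^2))) /
      (2 * pi * 10.5 * 3.8 * sqrt(1 - om^2))
  }, numeric(1))
  ls1 <- likelihoodSurface(list(id = "t", d2H = x, d34S = y), isoH, isoS, cv)
  expect_equal(as.vector(ls1@mass), byHand / sum(byHand), tolerance = 1e-12)
})

test_that("odds-ratio binarization keeps the highest-mass cells", {
  # uniform 3-cell surface at 2:1: exactly 2 cells (2/3 >= 2/3)
  u <- massSurface(c(1, 1, 1))
  b <- oddsBinarize(u, 2)
  expect_equal(sum(b@included), 2L)
  expect_equal(b@includedMass, 2 / 3, tolerance = 1e-12)
  # masses 0.5/0.3/0.15/0.05 at 2:1: cells 1-2 (0.8 >= 2/3)
  s <- massSurface(c(0.5, 0.3, 0.15, 0.05))
  b2 <- oddsBinarize(s, 2)
  expect_equal(rmVec(b2@included), c(1L, 1L, 0L, 0L))
  # same masses at 4:1: still cells 1-2, boundary-inclusive (0.8 >= 0.8)
  b4 <- oddsBinarize(s, 4)
  expect_equal(rmVec(b4@included), c(1L, 1L, 0L, 0L))
  expect_error(oddsBinarize(s, 0), "odds > 0")
})

test_that("2:1 regions nest inside 4:1 regions", {
  set.seed(11)
  for (i in 1:20) {
    s <- massSurface(rexp(30))
    in2 <- rmVec(oddsBinarize(s, 2)@included)
    in4 <- rmVec(oddsBinarize(s, 4)@included)
    expect_true(all(in4[in2 == 1L] == 1L))
    # included mass lies in [odds/(odds+1), 1]
    expect_gte(oddsBinarize(s, 2)@includedMass, 2 / 3 - 1e-12)
    expect_lte(oddsBinarize(s, 2)@includedMass, 1)
  }
})

test_that("binarization is minimal up to the boundary cell", {
  set.seed(12)
  s <- massSurface(rexp(40))
  b <- oddsBinarize(s, 2)
  v <- rmVec(s@mass)
  inc <- rmVec(b@included) == 1L
  lowest <- min(v[inc])
  expect_lt(b@includedMass - lowest, 2 / 3)
})

test_that("summed binary surfaces equal a brute-force recount", {
  cfg <- simConfig(seed = 3, gridCell = 20)
  fH <- generateTrueField(cfg, "d2H"); fS <- generateTrueField(cfg, "d34S")
  g <- gridSpec(0, 340, 0, 530, cell = 20)
  isoH <- fieldIsoscape(fH, g, "d2H"); isoS <- fieldIsoscape(fS, g, "d34S")
  cv <- covStructure(10.5, 3.8, 0.29)
  birds <- simulateKnownOrigins(cfg, fH, fS, n = 35, age = "ASY")
  surfaces <- lapply(seq_len(35), function(i)
    oddsBinarize(likelihoodSurface(birds[i, ], isoH, isoS, cv), 2))
  sm <- sumBinarySurfaces(surfaces)
  stack <- sapply(surfaces, function(s) as.vector(s@included))
  expect_equal(as.vector(sm$counts), rowSums(stack))
  expect_lte(max(sm$counts), 35)
  # identity and disjoint-union cases
  one <- sumBinarySurfaces(surfaces[1])
  expect_equal(one$counts, surfaces[[1]]@included)
  a <- massSurface(c(1, 0, 0, 0)); b <- massSurface(c(0, 0, 0, 1))
  dis <- sumBinarySurfaces(list(oddsBinarize(a, 1), oddsBinarize(b, 1)))
  expect_equal(max(dis$counts), 1L)
})
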