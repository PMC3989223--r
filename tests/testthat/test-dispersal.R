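# rectangular capture areas make the point-in-polygon ground truth a plain
# coordinate comparison, independent of the implementation's polygon test
rectPoly <- function(x1, x2, y1, y2)
  cbind(x = c(x1, x2, x2, x1), y = c(y1, y1, y2, y2))

test_that("residency follows overlap between region and capture area", {
  full <- massSurface(rep(1, 8))
  bAll <- oddsBinarize(full, 2)
  bAll@included[] <- 1L  # all cells included
  call <- classifyResidency(bAll, rectPoly(0, 2, 0, 1))
  expect_true(call$resident)
  expect_equal(call$min_dispersal_km, 0)
  # region entirely outside the capture area: immigrant
  s <- massSurface(c(0, 0, 0, 0, 0, 0, 1, 1))
  bOut <- oddsBinarize(s, 2)
  callOut <- classifyResidency(bOut, rectPoly(0, 2, 0, 1))
  expect_false(callOut$resident)
  expect_gt(callOut$min_dispersal_km, 0)
  # empty surface cannot be classified
  bEmpty <- bOut
  bEmpty@included[] <- 0L
  expect_error(classifyResidency(bEmpty, rectPoly(0, 2, 0, 1)), "empty")
})

test_that("residency calls match a brute-force recount on a cohort", {
  cfg <- simConfig(seed = 6, gridCell = 20)
  fH <- generateTrueField(cfg, "d2H"); fS <- generateTrueField(cfg, "d34S")
  g <- gridSpec(0, 340, 0, 530, cell = 20)
  isoH <- fieldIsoscape(fH, g, "d2H"); isoS <- fieldIsoscape(fS, g, "d34S")
  cv <- covStructure(10.5, 3.8, 0.29)
  birds <- simulateKnownOrigins(cfg, fH, fS, n = 20, age = "ASY")
  area <- rectPoly(100, 180, 200, 240)
  for (i in seq_len(20)) {
    bs <- oddsBinarize(likelihoodSurface(birds[i, ], isoH, isoS, cv), 2)
    call <- classifyResidency(bs, area)
    xy <- dualscape:::cellXY(g, which(rmVec(bs@included) == 1L))
    inside <- xy[, "x"] > 100 & xy[, "x"] < 180 &
      xy[, "y"] > 200 & xy[, "y"] < 240
    expect_equal(call$resident, any(inside))
  }
})

test_that("minimum dispersal distance is an exhaustive nearest-cell scan", {
  # single included cell 3 km east and 4 km north of the breeding point
  g <- gridSpec(0, 10, 0, 10, cell = 1)
  inc <- matrix(0L, 10, 10)
  inc[8, 5] <- 1L   # center (4.5, 7.5)
  bs <- new("BinarySurface", id = "t", odds = 2, grid = g, included = inc,
            includedMass = 1)
  expect_equal(minDispersalDistance(bs, c(1.5, 3.5)), 5)
  # breeding point inside an included cell: 0
  expect_equal(minDispersalDistance(bs, c(4.7, 7.2)), 0)
  # random surfaces: equality with a brute-force scan over included cells
  set.seed(9)
  for (i in 1:10) {
    inc2 <- matrix(rbinom(100, 1, 0.2), 10, 10)
    if (!any(inc2 == 1L)) inc2[1, 1] <- 1L
    bs2 <- new("BinarySurface", id = "r", odds = 2, grid = g,
               included = inc2, includedMass = 1)
    pt <- runif(2, -5, 15)
    xy <- dualscape:::cellXY(g, which(rmVec(inc2) == 1L))
    brute <- min(sqrt((xy[, "x"] - pt[1])^2 + (xy[, "y"] - pt[2])^2))
    got <- minDispersalDistance(bs2, pt)
    if (got > 0) expect_equal(got, brute, tolerance = 1e-12)
    else expect_lte(brute, sqrt(2) / 2)  # point inside an included cell
  }
})

test_that("minimum detectable distance reflects isoscape contrast", {
  g <- gridSpec(0, 100, 0, 100, cell = 5)
  cc <- cellCenters(g)
  cv <- covStructure(10.5, 3.8, 0.29)
  mk <- function(v, lab) new("Isoscape", isotope = lab, grid = g,
    mean = matrix(v, g@ny, g@nx, byrow = TRUE),
    variance = matrix(0, g@ny, g@nx),
    model = variogramModel("linear", 0, 1, 1), rmse = NA_real_)
  # strong gradients: small finite blind spot
  isoH <- mk(-120 + 0.9 * cc$x, "d2H")
  isoS <- mk(2 + 0.15 * cc$y, "d34S")
  d <- minDetectableDistance(isoH, isoS, cv, c(50, 50), odds = 2)
  expect_true(is.finite(d))
  expect_lt(d, 60)
  # brute-force scan over excluded cells reproduces the distance
  fict <- list(id = "f", d2H = -120 + 0.9 * 52.5, d34S = 2 + 0.15 * 52.5)
  bs <- oddsBinarize(likelihoodSurface(fict, isoH, isoS, cv), 2)
  xy <- dualscape:::cellXY(g, which(rmVec(bs@included) == 0L))
  brute <- min(sqrt((xy[, "x"] - 50)^2 + (xy[, "y"] - 50)^2))
  expect_equal(d, brute, tolerance = 1e-12)
  # featureless isoscapes whose HDR swallows every cell: not detectable
  g2 <- gridSpec(0, 100, 0, 100, cell = 50)
  mk2 <- function(v, lab) new("Isoscape", isotope = lab, grid = g2,
    mean = matrix(v, 2, 2), variance = matrix(0, 2, 2),
    model = variogramModel("linear", 0, 1, 1), rmse = NA_real_)
  expect_warning(
    dFlat <- minDetectableDistance(mk2(rep(-70, 4), "d2H"),
                                   mk2(rep(7, 4), "d34S"),
                                   cv, c(50, 50), odds = 4),
    "not detectable")
  expect_identical(dFlat, Inf)
})

test_that("classification accuracy is a plain percentage", {
  expect_equal(classificationAccuracy(rep(TRUE, 10)), 100)
  expect_equal(classificationAccuracy(c(rep(TRUE, 22), FALSE)),
               100 * 22 / 23)
  expect_error(classificationAccuracy(logical(0)), "no known-origin")
})

test_that("larger odds ratios give larger regions and more residents", {
  cfg <- simConfig(seed = 14, gridCell = 20)
  fH <- generateTrueField(cfg, "d2H"); fS <- generateTrueField(cfg, "d34S")
  g <- gridSpec(0, 340, 0, 530, cell = 20)
  isoH <- fieldIsoscape(fH, g, "d2H"); isoS <- fieldIsoscape(fS, g, "d34S")
  cv <- covStructure(10.5, 3.8, 0.29)
  birds <- simulateKnownOrigins(cfg, fH, fS, n = 15, age = "ASY")
  area <- rectPoly(120, 200, 220, 280)
  pt <- c(160, 250)
  res2 <- res4 <- logical(15)
  for (i in seq_len(15)) {
    ls1 <- likelihoodSurface(birds[i, ], isoH, isoS, cv)
    b2 <- oddsBinarize(ls1, 2); b4 <- oddsBinarize(ls1, 4)
    # min dispersal distance nonincreasing in odds
    expect_lte(minDispersalDistance(b4, pt), minDispersalDistance(b2, pt))
    res2[i] <- classifyResidency(b2, area)$resident
    res4[i] <- classifyResidency(b4, area)$resident
  }
  expect_gte(mean(res4), mean(res2))
})

test_that("distances are invariant under rigid translation of the frame", {
  g <- gridSpec(0, 50, 0, 50, cell = 5)
  set.seed(21)
  inc <- matrix(rbinom(100, 1, 0.15), 10, 10)
  inc[3, 7] <- 1L
  mkbs <- function(grid) new("BinarySurface", id = "t", odds = 2,
                             grid = grid, included = inc, includedMass = 1)
  pt <- c(2, 48)
  shift <- c(137, -52)
  gShift <- gridSpec(shift[1], 50 + shift[1], shift[2], 50 + shift[2],
                     cell = 5)
  expect_equal(minDispersalDistance(mkbs(g), pt),
               minDispersalDistance(mkbs(gShift), pt + shift),
               tolerance = 1e-12)
})
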