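test_that("polygon metrics match closed forms and the printed calibration", {
  sq <- unitSquare()
  m <- polygonMetrics(sq)
  expect_equal(m$area, 1)
  expect_equal(m$perimeter, 4)
  expect_equal(m$circularity, pi / 4)
  # calibrated: 0.5199 um/px squares the calibration for areas
  mc <- polygonMetrics(sq, calib = 0.5199)
  expect_equal(mc$area, 0.27029601, tolerance = 1e-12)
  expect_equal(mc$perimeter, 4 * 0.5199)
  # circularity is unit-free
  expect_equal(mc$circularity, m$circularity)
})

test_that("circularity is bounded by 1 and approached by regular n-gons", {
  expect_gte(polygonMetrics(regularPolygon(64))$circularity, 0.999)
  expect_lte(polygonMetrics(regularPolygon(64))$circularity, 1 + 1e-9)
  vals <- vapply(c(8, 16, 32, 64, 128), function(n)
    polygonMetrics(regularPolygon(n))$circularity, numeric(1))
  expect_true(all(diff(vals) > 0))
  set.seed(42)
  for (i in 1:20) {
    poly <- ellipsePolygon(runif(1, 1, 5), runif(1, 1, 5), n = 24)
    poly <- poly * (1 + matrix(rnorm(48, 0, 0.03), ncol = 2))
    expect_lte(polygonMetrics(poly)$circularity, 1 + 1e-9)
  }
})

test_that("degenerate polygons are rejected", {
  expect_error(polygonArea(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate|zero area")
  expect_error(polygonArea(cbind(c(0, 1), c(0, 0))), "3 vertices")
  expect_error(ellipseFit(cbind(c(0, 1, 2), c(0, 1, 2))))
})

test_that("polygon IoU matches exact values and a rasterization oracle", {
  sq <- unitSquare()
  expect_equal(polygonIoU(sq, sq), 1)
  expect_equal(polygonIoU(sq, unitSquare(cx = 5)), 0)
  off <- unitSquare(cx = 0.5)
  expect_equal(polygonIoU(sq, off), 1 / 3, tolerance = 1e-7)
  expect_equal(polygonIoU(off, sq), polygonIoU(sq, off))
  # random noisy ellipses against the subpixel-grid oracle
  set.seed(7)
  for (i in 1:10) {
    a <- ellipsePolygon(runif(1, 3, 8), runif(1, 3, 8), n = 24,
                        cx = runif(1, -2, 2), cy = runif(1, -2, 2))
    b <- rotatePolygon(ellipsePolygon(runif(1, 3, 8), runif(1, 3, 8), n = 24,
                                      cx = runif(1, -2, 2)), runif(1, 0, 180))
    expect_equal(polygonIoU(a, b), oracleIoU(a, b, step = 0.1), tolerance = 0.02)
  }
})

test_that("ellipse fit recovers eccentricity and orientation", {
  ell <- ellipsePolygon(2, 1)
  ef <- ellipseFit(ell)
  expect_equal(ef$eccentricity, sqrt(3) / 2, tolerance = 1e-3)
  expect_equal(ef$orientation, 0, tolerance = 1e-6)
  expect_equal(ef$major / ef$minor, 2, tolerance = 1e-3)
  # circle: isotropic convention
  cf <- ellipseFit(regularPolygon(64))
  expect_equal(cf$eccentricity, 0)
  expect_equal(cf$orientation, 0)
  # rotated by 45 degrees
  expect_equal(ellipseFit(rotatePolygon(ell, 45))$orientation, 45,
               tolerance = 0.5)
})

test_that("orientation is equivariant under rotation modulo 180", {
  base <- ellipsePolygon(3, 1.5)   # aspect 2 >= 1.2, well conditioned
  o0 <- ellipseFit(base)$orientation
  for (theta in c(10, 30, 60, 100, 150, 179)) {
    # rotatePolygon uses the mathematical convention; in the y-down image
    # frame the same matrix still adds theta to the reported angle mod 180
    ori <- ellipseFit(rotatePolygon(base, theta))$orientation
    d <- abs(((ori - o0 - theta) + 90) %% 180 - 90)
    expect_lt(d, 0.5)
  }
})

test_that("shape ratios: convex shapes, unit square, plus sign", {
  sq <- unitSquare()
  sr <- shapeRatios(sq)
  expect_equal(sr$solidity, 1)
  expect_equal(sr$boundary_smoothness, 1)
  expect_equal(sr$aspect_ratio, 1, tolerance = 1e-9)
  expect_equal(sr$fill_factor, 1)
  hexa <- shapeRatios(regularPolygon(6))
  expect_equal(hexa$solidity, 1)
  expect_equal(hexa$boundary_smoothness, 1)
  # plus sign of 5 unit squares: area 5; its convex hull is the corner-cut
  # octagon of area 7 (each of the 4 corners cuts a half-unit triangle off
  # the 3x3 box); the bounding box is the 3x3 square
  plus <- plusPolygon()
  # oracle: rasterize polygon and hull on a fine grid
  hull <- plus[grDevices::chull(plus[, 1], plus[, 2]), ]
  gx <- seq(-0.05, 3.05, by = 0.01)
  px <- rep(gx, times = length(gx)); py <- rep(gx, each = length(gx))
  oracleSolidity <- sum(oraclePointsInPolygon(plus, px, py)) /
    sum(oraclePointsInPolygon(hull, px, py))
  expect_equal(oracleSolidity, 5 / 7, tolerance = 0.01)
  psr <- shapeRatios(plus)
  expect_equal(psr$solidity, 5 / 7, tolerance = 1e-9)
  expect_equal(psr$fill_factor, 5 / 9, tolerance = 1e-9)
  expect_lt(psr$boundary_smoothness, 1)
})

test_that("rasterization follows the pixel-center rule", {
  # [0,10] x [0,10]: the half-open crossing rule keeps exactly one of each
  # pair of opposite boundary rows/columns, giving a 10 x 10 pixel block
  px <- rasterizePolygon(unitSquare(side = 10))
  expect_equal(nrow(px), 100)
  expect_true(all(px >= 0 & px <= 9))
  # oracle agreement on a rotated ellipse
  poly <- rotatePolygon(ellipsePolygon(8, 4, cx = 10, cy = 10), 30,
                        about = c(10, 10))
  got <- rasterizePolygon(poly)
  grid <- expand.grid(x = 0:20, y = 0:20)
  want <- oraclePointsInPolygon(poly, grid$x, grid$y)
  expect_equal(nrow(got), sum(want))
})

test_that("appearance vector has 24 unit-norm components", {
  set.seed(3)
  for (i in 1:5) {
    poly <- ellipsePolygon(runif(1, 4, 10), runif(1, 4, 10), cx = 15, cy = 15)
    img <- matrix(runif(40 * 40), 40, 40)
    v <- appearanceVector(poly, img)
    expect_length(v, 24)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)
  }
  # without an image the intensity block is zero
  v0 <- appearanceVector(ellipsePolygon(6, 4, cx = 8, cy = 8))
  expect_length(v0, 24)
  expect_equal(sqrt(sum(v0^2)), 1, tolerance = 1e-9)
  expect_true(all(v0[1:7] == 0))
})

test_that("uniform patches zero the dispersion intensity slots", {
  poly <- ellipsePolygon(6, 4, cx = 10, cy = 10)
  img <- matrix(0.5, 24, 24)
  v <- appearanceVector(poly, img)
  # sd, skewness, kurtosis slots (2, 6, 7) are zero before normalization,
  # hence zero after
  expect_equal(unname(v[c(2, 6, 7)]), c(0, 0, 0))
})

test_that("appearance vector is invariant to integer translation", {
  poly <- rotatePolygon(ellipsePolygon(7, 4, cx = 12, cy = 12), 25)
  set.seed(9)
  img <- matrix(runif(60 * 60), 60, 60)
  v1 <- appearanceVector(poly, img)
  # translate polygon and image content together by (5, 3)
  img2 <- matrix(0, 60, 60)
  img2[(1:57) + 3, (1:55) + 5] <- img[1:57, 1:55]
  v2 <- appearanceVector(sweep(poly, 2, c(5, 3), "+"), img2)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("appearance vector rejects empty rasterizations", {
  sliver <- cbind(c(0.1, 0.9, 0.5), c(0.1, 0.1, 0.4))
  expect_error(appearanceVector(sliver), "zero pixels")
})
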