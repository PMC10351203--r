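# Series solution for laminar flow in a rectangular duct (width a, height
# b, both um): an independent oracle for the grid solver on a polygonal
# domain. Q per unit pressure gradient from the classic Fourier series.
rectDuctResistance <- function(a, b, mu) {
  am <- a * 1e-6; bm <- b * 1e-6
  k <- seq(1, 199, by = 2)
  s <- sum(tanh(k * pi * bm / (2 * am)) / k^5)
  Q <- (am^3 * bm / (12 * mu)) * (1 - (192 / pi^5) * (am / bm) * s)
  1 / Q
}

test_that("closed-form resistances scale as expected", {
  expect_equal(circleResistance(25, 7.058e-4), 4.601e15, tolerance = 1e-3)
  expect_equal(circleResistance(50) / circleResistance(25), 1 / 16,
               tolerance = 1e-12)
  expect_equal(circleResistance(25, 2 * 7.058e-4) / circleResistance(25), 2)

  ## annulus: circle limit, lubrication divergence, monotone gap closing
  ## the circle limit is approached logarithmically in r1
  expect_equal(annulusResistance(1e-60, 30), circleResistance(30),
               tolerance = 0.01)
  expect_gt(annulusResistance(1e-4, 30), annulusResistance(1e-60, 30))
  gaps <- vapply(c(10, 5, 2, 1, 0.5), function(g)
    annulusResistance(20, 20 + g), numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_error(annulusResistance(20, 20), "r2 > r1")
})

test_that("optimal elliptical annulus approximation matches its anchors", {
  expect_equal(optimalAnnulusResistance(1.4, 23), 8.7e15, tolerance = 0.01)
  expect_equal(optimalAnnulusResistance(1, 20), 2.94e16, tolerance = 1e-3)
  ## strictly decreasing in K at fixed radius
  ks <- vapply(seq(0.5, 3, by = 0.5), optimalAnnulusResistance, numeric(1),
               r1 = 20)
  expect_true(all(diff(ks) < 0))
  ## the as-printed form is exposed but differs by many orders of magnitude
  expect_false(isTRUE(all.equal(
    optimalAnnulusResistance(1.4, 23, form = "printed"),
    optimalAnnulusResistance(1.4, 23), tolerance = 0.5)))
})

test_that("grid Poiseuille solver matches circle and annulus closed forms", {
  for (a in c(10, 20, 40)) {
    s <- solvePoiseuille(new("CircleFit", center = c(0, 0), r1 = a))
    expect_lt(abs(s@resistance - circleResistance(a)) / circleResistance(a),
              0.01)
    expect_lt(s@meshStats$calibrationError, 0.01)
  }
  ann <- new("EllipseAnnulusFit", center = c(0, 0), r2 = 31, r3 = 31,
             angle = 0, oH = 0, oV = 0, r1 = 20)
  s <- solvePoiseuille(ann)
  expect_lt(abs(s@resistance - annulusResistance(20, 31)) /
              annulusResistance(20, 31), 0.01)
  ann2 <- new("EllipseAnnulusFit", center = c(0, 0), r2 = 40, r3 = 40,
              angle = 0, oH = 0, oV = 0, r1 = 20)
  s2 <- solvePoiseuille(ann2)
  expect_lt(abs(s2@resistance - annulusResistance(20, 40)) /
              annulusResistance(20, 40), 0.01)
})

test_that("solver velocity field and linearity behave physically", {
  s <- solvePoiseuille(new("CircleFit", center = c(0, 0), r1 = 20))
  expect_true(all(s@velocity$u > 0))
  s2 <- solvePoiseuille(new("CircleFit", center = c(0, 0), r1 = 20),
                        gradient = 1000)
  expect_equal(s2@flowRate / s@flowRate, 2, tolerance = 1e-12)
  expect_equal(s2@resistance, s@resistance, tolerance = 1e-12)

  ## domain monotonicity: enlarging the domain cannot raise resistance
  rs <- vapply(c(10, 14, 20), function(a)
    solvePoiseuille(new("CircleFit", center = c(0, 0), r1 = a))@resistance,
    numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("polygon domains: rectangle oracle and parallel lobes", {
  rect <- ringsToFlowDomain(list(list(x = c(0, 40, 40, 0), y = c(0, 0, 10, 10))))
  s <- solvePoiseuille(rect)
  expect_equal(s@resistance, rectDuctResistance(10, 40, 7.058e-4),
               tolerance = 0.01)

  ## two disjoint circular lobes act as parallel channels: flow rates add
  two <- ringsToFlowDomain(list(
    list(x = 12 * cos(seq(0, 2 * pi, length.out = 73)[-73]) - 20,
         y = 12 * sin(seq(0, 2 * pi, length.out = 73)[-73])),
    list(x = 9 * cos(seq(0, 2 * pi, length.out = 73)[-73]) + 20,
         y = 9 * sin(seq(0, 2 * pi, length.out = 73)[-73]))))
  st <- solvePoiseuille(two)
  qExp <- 500 / circleResistance(12) + 500 / circleResistance(9)
  expect_equal(st@flowRate, qExp, tolerance = 0.02)
})

test_that("mask domains: erosion, tracing and resistance increase", {
  expect_error(maskToFlowDomain(matrix(TRUE, 3, 3), 1), "one-pixel erosion")

  sq <- matrix(FALSE, 26, 26); sq[4:23, 4:23] <- TRUE
  d <- maskToFlowDomain(sq, 1)
  expect_length(d$rings, 1)
  expect_equal(pvsmorph:::ringsArea(d$rings), 18^2, tolerance = 0.01)
  expect_equal(diff(d$bbox[1:2]), 18, tolerance = 0.01)

  ## one-pixel erosion strictly increases resistance
  disk <- matrix(FALSE, 61, 61)
  off <- seq_len(61) - 31
  disk[outer(off^2, off^2, `+`) <= 22^2] <- TRUE
  r1 <- solvePoiseuille(maskToFlowDomain(disk, 1))@resistance
  er <- EBImage::erode(EBImage::Image(disk * 1), EBImage::makeBrush(3, "box")) > 0.5
  r2 <- solvePoiseuille(maskToFlowDomain(er, 1))@resistance
  expect_gt(r2, r1)
})

test_that("resistance of a scaled family follows the -2 area power law", {
  sh <- polynomialShape(20, 30, 45, h1 = 28, h2 = 16, h3 = 7, hC = -1)
  pg <- asPolygon(sh)
  vals <- vapply(c(0.5, 0.707, 1, 1.414, 2), function(sc) {
    rings <- lapply(pg$rings, function(r) list(x = r$x * sc, y = r$y * sc))
    sol <- solvePoiseuille(ringsToFlowDomain(rings))
    c(pvsmorph:::ringsArea(rings), sol@resistance)
  }, numeric(2))
  fit <- powerLawFit(vals[1, ], vals[2, ])
  expect_equal(fit$exponent, -2, tolerance = 0.02)
})

test_that("segment resistance is the resistors-in-series mean", {
  s <- segmentResistance(rep(4e15, 10), spacing = 0.8)
  expect_equal(s$total, 4e15 * 8e-6, tolerance = 1e-12)
  s2 <- segmentResistance(c(1, 3) * 1e15, spacing = 2)
  expect_equal(s2$total, 2e15 * 4e-6)
  s3 <- segmentResistance(5e15, spacing = 0.8)
  expect_equal(s3$total, 5e15 * 0.8e-6)
  expect_error(segmentResistance(numeric(0), 1), "no per-section")
})
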