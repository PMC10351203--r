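diskSection <- function(r = 15, n = 41, p = 1, raggedBottom = 0) {
  off <- (seq_len(n) - (n + 1) / 2) * p
  H <- matrix(off, n, n); V <- matrix(off, n, n, byrow = TRUE)
  m <- H^2 + V^2 <= r^2
  if (raggedBottom > 0) {
    ## under-segmented bottom: random inward bites where the shadowed
    ## signal is lost, the scenario the hull exclusion compensates for
    set.seed(99)
    bites <- V < -r / 3 & H^2 + V^2 > (r - raggedBottom)^2 &
      matrix(runif(n * n) < 0.6, n, n)
    m <- m & !bites
  }
  new("VesselSection", vessel = m, pvs = matrix(FALSE, n, n), pixelSize = p,
      center = c((n + 1) / 2, (n + 1) / 2), arclength = 0,
      edgeDistance = Inf, outOfBounds = FALSE)
}

test_that("vessel circle fit recovers disks and rejects degenerate masks", {
  f <- fitVesselCircle(diskSection())
  expect_lt(abs(f@r1 - 15), 0.5)
  expect_lt(max(abs(f@center)), 0.5)

  ## under-segmented bottom: hull exclusion keeps the radius honest
  fb <- fitVesselCircle(diskSection(raggedBottom = 4))
  expect_lt(abs(fb@r1 - 15), 1)

  two <- diskSection()
  m <- matrix(FALSE, 41, 41); m[20:21, 20] <- TRUE
  two@vessel <- m
  expect_error(fitVesselCircle(two), "boundary")
})

test_that("ellipse fit reproduces moments, symmetry and equivariance", {
  n <- 81; p <- 1
  off <- (seq_len(n) - (n + 1) / 2) * p
  H <- matrix(off, n, n); V <- matrix(off, n, n, byrow = TRUE)
  mk <- function(a, b, m) {
    s <- new("VesselSection", vessel = matrix(FALSE, n, n), pvs = m,
             pixelSize = p, center = c((n + 1) / 2, (n + 1) / 2),
             arclength = 0, edgeDistance = Inf, outOfBounds = FALSE)
    fitEllipse(s, new("CircleFit", center = c(0, 0), r1 = 5))
  }
  ell <- (H / 20)^2 + (V / 8)^2 <= 1
  f <- mk(20, 8, ell)
  expect_lt(abs(f@r2 - 20), 0.5)
  expect_lt(abs(f@r3 - 8), 0.5)
  expect_lt(abs(f@angle), 0.02)
  ## symmetric mask about the vessel center: zero offsets
  expect_lt(max(abs(c(f@oH, f@oV))), 0.5)
  ## 90-degree rotation: axes unchanged, angle shifts by pi/2
  f90 <- mk(8, 20, t(ell))
  expect_lt(abs(f90@r2 - f@r2), 1e-6)
  expect_lt(abs(abs(f90@angle - f@angle) - pi / 2), 0.02)

  ## moment identity: moments of the rasterized fitted ellipse match the
  ## mask's within 2%
  ca <- cos(f@angle); sa <- sin(f@angle)
  A <- (H - f@center[1]) * ca + (V - f@center[2]) * sa
  B <- -(H - f@center[1]) * sa + (V - f@center[2]) * ca
  refit <- (A / f@r2)^2 + (B / f@r3)^2 <= 1
  mom <- function(m) {
    x <- H[m]; y <- V[m]
    c(var(x) * (length(x) - 1) / length(x),
      var(y) * (length(y) - 1) / length(y))
  }
  expect_lt(max(abs(mom(refit) - mom(ell)) / mom(ell)), 0.02)
  expect_error(mk(1, 1, matrix(FALSE, n, n)), "empty")
})

test_that("translation equivariance of circle and ellipse fits", {
  sec <- diskSection(r = 10, n = 61)
  shift <- function(m, k) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + k):nrow(m), ] <- m[1:(nrow(m) - k), ]
    out
  }
  sec2 <- sec; sec2@vessel <- shift(sec@vessel, 7)
  f1 <- fitVesselCircle(sec); f2 <- fitVesselCircle(sec2)
  expect_lt(abs(f2@center[1] - f1@center[1] - 7), 0.2)
  expect_lt(abs(f2@r1 - f1@r1), 0.05)
})

test_that("the canonical spline geometry matches its published profile", {
  s <- splineShape(1)
  ## the tapered end: full height at the last control point is R1/4.5
  top <- pvsmorph:::splineTopFun(s)
  expect_equal(2 * top(5), 1 / 4.5, tolerance = 1e-3)
  expect_equal(s@minEndWidth, 1 / 4.5)
  ## area ratio at the published peak, and invariant to the vessel radius
  expect_equal(areaRatio(s), 1.48, tolerance = 0.02)
  ks <- vapply(c(5, 20, 50), function(r) areaRatio(splineShape(r)), numeric(1))
  expect_lt(max(ks) - min(ks), 1e-6)
  ## doubling r1 quadruples the PVS area
  expect_equal(shapeArea(splineShape(10)) / shapeArea(splineShape(5)), 4,
               tolerance = 1e-6)
  expect_s4_class(buildSplineShape(new("CircleFit", center = c(0, 0), r1 = 3)),
                  "SplineShape")
})

test_that("polynomial fit recovers noise-free truths within one pixel", {
  set.seed(42)
  maxErr <- 0
  for (i in 1:50) {
    sh <- randomQuartileShape()
    f <- fitSection(rasterizeSection(sh))
    fp <- f$polynomial
    errs <- c(fp@wLeft - sh@wLeft, fp@wRight - sh@wRight,
              fp@h1Left - sh@h1Left, fp@h1Right - sh@h1Right,
              fp@h2Left - sh@h2Left, fp@h2Right - sh@h2Right,
              fp@h3Left - sh@h3Left, fp@h3Right - sh@h3Right,
              fp@hC - sh@hC)
    maxErr <- max(maxErr, abs(errs))
  }
  expect_lt(maxErr, 0.648)  # one acquisition pixel
})

test_that("disconnected lobes give a negative connection height", {
  sh <- polynomialShape(10, 15, 15, h1 = 8, h2 = 5, h3 = 2, hC = -2)
  sec <- rasterizeSection(sh)
  f <- fitSection(sec)
  expect_lt(f$polynomial@hC, 0)
  ## and the polygon export splits into two lobes
  pg <- asPolygon(sh)
  expect_equal(length(pg$rings), 2)
})

test_that("the published peak-parameter shape is constructible", {
  sh <- polynomialShape(r1 = 20.8, wLeft = 22.3, wRight = 42.1,
                        h1 = 39.5, h2 = 18.6, h3 = 9.37, hC = 0.799)
  pg <- asPolygon(sh)
  expect_gt(pg$area, 0)
  expect_equal(pg$area, shapeArea(sh), tolerance = 0.01)
  ## round trip through the fit reproduces the parameters
  f <- fitSection(rasterizeSection(sh))
  expect_lt(abs(f$polynomial@hC - 0.799), 0.648)
})

test_that("polygon export respects geometry and topology", {
  circ <- new("CircleFit", center = c(0, 0), r1 = 7)
  pg <- asPolygon(circ)
  expect_lt(abs(pg$area - pi * 49) / (pi * 49), 0.001)

  conc <- new("EllipseAnnulusFit", center = c(0, 0), r2 = 30, r3 = 25,
              angle = 0, oH = 0, oV = 0, r1 = 10)
  pgc <- asPolygon(conc)
  expect_equal(length(pgc$rings), 2)
  expect_equal(sum(vapply(pgc$rings, `[[`, logical(1), "hole")), 1L)
  expect_equal(pgc$area, pi * 30 * 25 - pi * 100, tolerance = 1e-3)

  ## ellipse thinner than the vessel: the difference splits into two lobes
  lobes <- new("EllipseAnnulusFit", center = c(0, 0), r2 = 30, r3 = 8,
               angle = 0, oH = 0, oV = 0, r1 = 10)
  expect_equal(length(asPolygon(lobes)$rings), 2)
})

test_that("area ratios follow their definitions", {
  expect_equal(areaRatio(50, 50), 1)
  expect_error(areaRatio(10, 0), "positive")
  sh <- polynomialShape(10, 15, 15, h1 = 8, h2 = 5, h3 = 2, hC = 1)
  expect_equal(areaRatio(sh), shapeArea(sh) / (pi * 100))

  ## segmented synthetic section: K within 5% of the analytic ratio
  sh2 <- randomQuartileShape()
  sec <- rasterizeSection(sh2)
  segK <- sum(sec@pvs) / sum(sec@vessel)
  expect_equal(segK, areaRatio(sh2), tolerance = 0.05)
})
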