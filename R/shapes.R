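## Idealized PVS cross-section geometries: construction, implicit fields,
## areas and polygon export. Fitting routines live in shapefits.R.

## Canonical spline control points in units of R1: horizontal stations
## 0..5 R1 and the vertical top boundary at each station. The tapered end
## height 2 x 0.1111 R1 equals R1/4.5.
.splineControl <- cbind(h = c(0, 1, 2, 3, 4, 5),
                        v = c(1.1111, 0.85, 0.2667, 0.1111, 0.1111, 0.1111))

#' Construct the canonical spline PVS shape
#'
#' Builds the two-lobed spline geometry from the canonical control points
#' scaled by the vessel radius: a cubic interpolating spline through the six
#' (horizontal, top-height) pairs defines the upper-right boundary, which is
#' mirrored across the vertical and horizontal axes; the vessel circle is
#' centered `0.0667 R1` below the PVS vertical midpoint. Since every length
#' scales with `r1`, the PVS-to-vessel area ratio is independent of `r1`.
#'
#' @param r1 vessel radius (um).
#' @return A [SplineShape-class].
#' @export
splineShape <- function(r1) {
  stopifnot(is.numeric(r1), length(r1) == 1, r1 > 0)
  new("SplineShape", r1 = r1, controlPoints = .splineControl * r1,
      oF = 0.0667 * r1, minEndWidth = r1 / 4.5)
}

#' @rdname splineShape
#' @param vessel a [CircleFit-class]; the spline geometry is built from its
#'   radius alone.
#' @export
buildSplineShape <- function(vessel) {
  stopifnot(is(vessel, "CircleFit"))
  splineShape(vessel@r1)
}

## Clamped (zero end-slope) cubic interpolating spline. The PVS outline is
## mirrored across the vertical axis at the first control point and closes
## onto its horizontal mirror at the last, so zero boundary slopes keep the
## mirrored outline C1; base R splinefun offers no clamped end condition.
.clampedSpline <- function(x, y, d0 = 0, dn = 0) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  A[1, 1] <- 2 * h[1]; A[1, 2] <- h[1]
  rhs[1] <- 6 * ((y[2] - y[1]) / h[1] - d0)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  A[n, n - 1] <- h[n - 1]; A[n, n] <- 2 * h[n - 1]
  rhs[n] <- 6 * (dn - (y[n] - y[n - 1]) / h[n - 1])
  M <- solve(A, rhs)  # second derivatives at the knots
  function(t) {
    i <- pmin(pmax(findInterval(t, x), 1), n - 1)
    hi <- h[i]; a <- (x[i + 1] - t) / hi; b <- (t - x[i]) / hi
    a * y[i] + b * y[i + 1] +
      ((a^3 - a) * M[i] + (b^3 - b) * M[i + 1]) * hi^2 / 6
  }
}

splineTopFun <- function(shape)
  .clampedSpline(shape@controlPoints[, 1], shape@controlPoints[, 2])

## Derived morphometric measures from polynomial-shape coefficients
## (vessel-centered frame). Shared by the synthetic ground truth and the
## least-squares fit so both report identical conventions.
.polyDerived <- function(r1, topLine, bottomLeft, bottomRight, wLeft, wRight) {
  vtop <- function(h) topLine[1] + topLine[2] * h
  qeval <- function(q, h) q[1] + q[2] * h + q[3] * h^2
  hts <- function(q, edge, w, sgn) {
    hh <- edge + sgn * c(0, w / 2, w)
    pmax(0, vtop(hh) - qeval(q, hh))
  }
  out <- list(hC = vtop(0) - r1,
              h1Left = NA_real_, h2Left = NA_real_, h3Left = NA_real_,
              h1Right = NA_real_, h2Right = NA_real_, h3Right = NA_real_)
  if (!is.null(bottomLeft)) {
    h <- hts(bottomLeft, -r1, wLeft, -1)
    out[c("h1Left", "h2Left", "h3Left")] <- as.list(h)
  }
  if (!is.null(bottomRight)) {
    h <- hts(bottomRight, r1, wRight, 1)
    out[c("h1Right", "h2Right", "h3Right")] <- as.list(h)
  }
  out
}

.newPolynomialShape <- function(r1, topLine, bottomLeft, bottomRight,
                                wLeft, wRight, center = c(0, 0)) {
  d <- .polyDerived(r1, topLine, bottomLeft, bottomRight, wLeft, wRight)
  new("PolynomialShape", r1 = r1, center = as.numeric(center),
      topLine = as.numeric(topLine),
      bottomLeft = bottomLeft, bottomRight = bottomRight,
      wLeft = if (is.null(bottomLeft)) NA_real_ else wLeft,
      wRight = if (is.null(bottomRight)) NA_real_ else wRight,
      h1Left = d$h1Left, h2Left = d$h2Left, h3Left = d$h3Left,
      h1Right = d$h1Right, h2Right = d$h2Right, h3Right = d$h3Right,
      hC = d$hC)
}

#' Construct a polynomial PVS shape from its morphometric parameters
#'
#' Builds the two-lobed geometry whose upper boundary is a line with height
#' `r1 + hC` above the vessel center at the vessel-center column, and whose
#' lobe lower boundaries are the unique quadratics giving the requested
#' heights H1 (at the vessel edge), H2 (midway along W) and H3 (at the far
#' end). This is the generative parameterization used by the synthetic
#' ground truth, and it is exactly representable by the least-squares fit.
#'
#' @param r1 vessel radius (um).
#' @param wLeft,wRight lobe widths from the vessel edge to the lobe end (um).
#' @param h1,h2,h3 lobe heights (um); recycled to both sides unless the
#'   side-specific values are given.
#' @param hC signed top-line height above the vessel top (um).
#' @param topSlope slope of the upper boundary line (default level).
#' @param h1Left,h2Left,h3Left,h1Right,h2Right,h3Right optional per-side
#'   heights overriding `h1`, `h2`, `h3`.
#' @param center vessel center in the section frame (um).
#' @return A [PolynomialShape-class].
#' @export
polynomialShape <- function(r1, wLeft, wRight, h1, h2, h3, hC = 0,
                            topSlope = 0,
                            h1Left = h1, h2Left = h2, h3Left = h3,
                            h1Right = h1, h2Right = h2, h3Right = h3,
                            center = c(0, 0)) {
  stopifnot(r1 > 0, wLeft > 0, wRight > 0)
  topLine <- c(r1 + hC, topSlope)
  vtop <- function(h) topLine[1] + topLine[2] * h
  solveQuad <- function(hh, vv) {
    as.numeric(solve(cbind(1, hh, hh^2), vv))
  }
  hR <- r1 + c(0, wRight / 2, wRight)
  qR <- solveQuad(hR, vtop(hR) - c(h1Right, h2Right, h3Right))
  hL <- -r1 - c(0, wLeft / 2, wLeft)
  qL <- solveQuad(hL, vtop(hL) - c(h1Left, h2Left, h3Left))
  .newPolynomialShape(r1, topLine, qL, qR, wLeft, wRight, center)
}

## Lower boundary of the polynomial region at vessel-centered columns h:
## lobe quadratics outside the vessel, the upper circular arc above it, and
## +Inf outside the shape's horizontal extent.
.polyBottom <- function(shape, h) {
  b <- rep(Inf, length(h))
  mid <- abs(h) < shape@r1
  b[mid] <- sqrt(pmax(0, shape@r1^2 - h[mid]^2))
  if (!is.null(shape@bottomRight)) {
    q <- shape@bottomRight
    i <- h >= shape@r1 & h <= shape@r1 + shape@wRight
    b[i] <- q[1] + q[2] * h[i] + q[3] * h[i]^2
  }
  if (!is.null(shape@bottomLeft)) {
    q <- shape@bottomLeft
    i <- h <= -shape@r1 & h >= -(shape@r1 + shape@wLeft)
    b[i] <- q[1] + q[2] * h[i] + q[3] * h[i]^2
  }
  b
}

## ---- implicit fields -------------------------------------------------------
## shapeField(fit, h, v) > 0 inside the PVS flow region (vessel excluded),
## continuous across the zero level so contour tracing is sub-pixel accurate.

setGeneric("shapeField", function(shape, h, v) standardGeneric("shapeField"))

setMethod("shapeField", "CircleFit", function(shape, h, v) {
  shape@r1 - sqrt((h - shape@center[1])^2 + (v - shape@center[2])^2)
})

setMethod("shapeField", "SplineShape", function(shape, h, v) {
  s <- splineTopFun(shape)
  hw <- max(shape@controlPoints[, 1])
  top <- s(pmin(abs(h), hw))
  dv <- sqrt(h^2 + (v + shape@oF)^2)
  pmin(top - abs(v), hw - abs(h), dv - shape@r1)
})

setMethod("shapeField", "PolynomialShape", function(shape, h, v) {
  h <- h - shape@center[1]; v <- v - shape@center[2]
  vtop <- shape@topLine[1] + shape@topLine[2] * h
  b <- .polyBottom(shape, h)
  f <- pmin(vtop - v, v - b)
  f[!is.finite(f)] <- -shape@r1
  hi <- if (is.null(shape@bottomRight)) shape@r1 else shape@r1 + shape@wRight
  lo <- if (is.null(shape@bottomLeft)) -shape@r1 else -(shape@r1 + shape@wLeft)
  pmin(f, hi - h, h - lo)
})

setMethod("shapeField", "EllipseAnnulusFit", function(shape, h, v) {
  dh <- h - shape@center[1]; dv <- v - shape@center[2]
  ca <- cos(shape@angle); sa <- sin(shape@angle)
  a <- dh * ca + dv * sa
  b <- -dh * sa + dv * ca
  fe <- shape@r3 * (1 - sqrt((a / shape@r2)^2 + (b / shape@r3)^2))
  dvess <- sqrt((dh - shape@oH)^2 + (dv - shape@oV)^2)
  pmin(fe, dvess - shape@r1)
})

## Conservative bounding box (um) of the PVS region, in the section frame.
setGeneric("shapeBBox", function(shape) standardGeneric("shapeBBox"))

setMethod("shapeBBox", "CircleFit", function(shape)
  c(shape@center[1] - shape@r1, shape@center[1] + shape@r1,
    shape@center[2] - shape@r1, shape@center[2] + shape@r1))

setMethod("shapeBBox", "SplineShape", function(shape) {
  hw <- max(shape@controlPoints[, 1])
  vmax <- max(shape@controlPoints[, 2]) * 1.2
  c(-hw, hw, -vmax, vmax)
})

setMethod("shapeBBox", "PolynomialShape", function(shape) {
  hi <- if (is.null(shape@bottomRight)) shape@r1 else shape@r1 + shape@wRight
  lo <- if (is.null(shape@bottomLeft)) -shape@r1 else -(shape@r1 + shape@wLeft)
  hh <- seq(lo, hi, length.out = 801)
  b <- .polyBottom(shape, hh)
  vtop <- shape@topLine[1] + shape@topLine[2] * hh
  ok <- is.finite(b) & vtop > b
  c(lo + shape@center[1], hi + shape@center[1],
    min(b[ok]) + shape@center[2], max(vtop[ok]) + shape@center[2])
})

setMethod("shapeBBox", "EllipseAnnulusFit", function(shape) {
  e <- sqrt((shape@r2 * cos(shape@angle))^2 + (shape@r3 * sin(shape@angle))^2)
  f <- sqrt((shape@r2 * sin(shape@angle))^2 + (shape@r3 * cos(shape@angle))^2)
  c(shape@center[1] - e, shape@center[1] + e,
    shape@center[2] - f, shape@center[2] + f)
})

## ---- areas -----------------------------------------------------------------

#' Analytic area of an idealized cross-section shape
#'
#' PVS shapes report the area of the perivascular region with the vessel
#' excluded; the circle fit reports the vessel lumen area.
#'
#' @param shape a shape-fit object.
#' @return Area in um^2.
#' @export
setGeneric("shapeArea", function(shape) standardGeneric("shapeArea"))

#' @rdname shapeArea
#' @export
setMethod("shapeArea", "CircleFit", function(shape) pi * shape@r1^2)

#' @rdname shapeArea
#' @export
setMethod("shapeArea", "SplineShape", function(shape) {
  s <- splineTopFun(shape)
  hw <- max(shape@controlPoints[, 1])
  4 * integrate(s, 0, hw, rel.tol = 1e-10)$value - pi * shape@r1^2
})

#' @rdname shapeArea
#' @export
setMethod("shapeArea", "PolynomialShape", function(shape) {
  hi <- if (is.null(shape@bottomRight)) shape@r1 else shape@r1 + shape@wRight
  lo <- if (is.null(shape@bottomLeft)) -shape@r1 else -(shape@r1 + shape@wLeft)
  hh <- seq(lo, hi, length.out = 8001)
  b <- .polyBottom(shape, hh)
  vtop <- shape@topLine[1] + shape@topLine[2] * hh
  ht <- pmax(0, vtop - b)
  ht[!is.finite(ht)] <- 0
  sum((ht[-1] + ht[-length(ht)]) / 2) * diff(hh[1:2])
})

#' @rdname shapeArea
#' @export
setMethod("shapeArea", "EllipseAnnulusFit", function(shape) {
  ## column-wise interval subtraction in the ellipse principal frame, where
  ## the vessel circle stays a circle
  ca <- cos(shape@angle); sa <- sin(shape@angle)
  cx <- shape@oH * ca + shape@oV * sa
  cy <- -shape@oH * sa + shape@oV * ca
  xs <- seq(-shape@r2, shape@r2, length.out = 8001)
  ye <- shape@r3 * sqrt(pmax(0, 1 - (xs / shape@r2)^2))
  lenE <- 2 * ye
  dx2 <- shape@r1^2 - (xs - cx)^2
  yc <- sqrt(pmax(0, dx2))
  loI <- pmax(-ye, cy - yc); hiI <- pmin(ye, cy + yc)
  lenI <- ifelse(dx2 > 0, pmax(0, hiI - loI), 0)
  len <- lenE - lenI
  sum((len[-1] + len[-length(len)]) / 2) * diff(xs[1:2])
})

#' PVS-to-vessel area ratio
#'
#' `K = pvsArea / vesselArea`. For idealized fits the denominator is the
#' fitted vessel circle area `pi R1^2`; for segmented sections it is the
#' segmented vessel area.
#'
#' @param pvs PVS area (um^2), or a PVS shape object.
#' @param vessel vessel area (um^2); ignored when `pvs` is a shape, whose
#'   own `r1` provides the denominator.
#' @return Dimensionless ratio K.
#' @export
areaRatio <- function(pvs, vessel) {
  if (is(pvs, "SplineShape") || is(pvs, "PolynomialShape") ||
      is(pvs, "EllipseAnnulusFit")) {
    r1 <- pvs@r1
    return(shapeArea(pvs) / (pi * r1^2))
  }
  stopifnot(is.numeric(pvs), is.numeric(vessel))
  if (any(vessel <= 0)) stop("vessel area must be positive")
  pvs / vessel
}

## ---- polygon export --------------------------------------------------------

#' Convert a shape fit to closed polygon rings
#'
#' Traces the zero level of the shape's implicit field on a regular grid.
#' Rings follow even-odd semantics: a ring nested inside another is a hole
#' (e.g. the vessel circle inside a wide elliptical annulus); a
#' disconnected shape yields one ring per lobe.
#'
#' @param shape a shape-fit object.
#' @param resolution grid points per um (default 8).
#' @return List with `rings` (each a list with x, y in um and a `hole`
#'   flag) and the even-odd enclosed `area` (um^2).
#' @export
asPolygon <- function(shape, resolution = 8) {
  bb <- shapeBBox(shape)
  step <- 1 / resolution
  ## the grid is offset by an irrational fraction of a step so grid lines
  ## never coincide with straight stretches of the zero level set
  xs <- seq(bb[1] - (3 + 0.3183) * step, bb[2] + 3 * step, by = step)
  ys <- seq(bb[3] - (3 + 0.2718) * step, bb[4] + 3 * step, by = step)
  g <- expand.grid(x = xs, y = ys)
  z <- matrix(shapeField(shape, g$x, g$y), length(xs), length(ys))
  z[z == 0] <- -1e-12
  cl <- contourLines(xs, ys, z, levels = 0)
  if (!length(cl)) stop("shape produced no boundary contour")
  rings <- list()
  for (r in cl) {
    n <- length(r$x)
    if (n < 4 || r$x[1] != r$x[n] || r$y[1] != r$y[n])
      stop("open boundary contour; shape extends beyond its bounding box")
    if (abs(ringArea(r$x[-n], r$y[-n])) < step^2) next  # grid-artifact sliver
    rings[[length(rings) + 1]] <- list(x = r$x[-n], y = r$y[-n])
  }
  if (!length(rings)) stop("shape produced only degenerate boundary rings")
  depth <- vapply(seq_along(rings), function(i)
    sum(vapply(seq_along(rings), function(j)
      if (i == j) FALSE else pointInRings(rings[[i]]$x[1], rings[[i]]$y[1],
                                          rings[j]), logical(1))), numeric(1))
  for (i in seq_along(rings)) rings[[i]]$hole <- depth[i] %% 2 == 1
  list(rings = rings, area = ringsArea(rings))
}

#' Rasterize a shape pair into a synthetic section
#'
#' Renders the vessel circle and a PVS shape into a [VesselSection-class]
#' at the given pixel pitch (pixel-center sampling), the direct 2D
#' counterpart of the 3D stack rasterization; used for parameter-recovery
#' experiments against known truths.
#'
#' @param shape a PVS shape object (its `r1` also draws the vessel disk).
#' @param pixelSize pixel pitch (um), default the acquisition pitch.
#' @param halfWidth image half-width (um); sized to the shape by default.
#' @return A [VesselSection-class] with `arclength` 0.
#' @export
rasterizeSection <- function(shape, pixelSize = 0.648, halfWidth = NULL) {
  bb <- shapeBBox(shape)
  if (is.null(halfWidth)) halfWidth <- max(abs(bb)) + 4 * pixelSize
  halfWidth <- pixelSize * ceiling(halfWidth / pixelSize)  # symmetric grid
  off <- seq(-halfWidth, halfWidth, by = pixelSize)
  n <- length(off)
  H <- matrix(off, n, n); V <- matrix(off, n, n, byrow = TRUE)
  ctr <- if (.hasSlot(shape, "center")) shape@center else c(0, 0)
  vess <- (H - ctr[1])^2 + (V - ctr[2])^2 <= shape@r1^2
  pvs <- matrix(shapeField(shape, as.numeric(H), as.numeric(V)) > 0, n, n) & !vess
  new("VesselSection", vessel = vess, pvs = pvs, pixelSize = pixelSize,
      center = c((n + 1) / 2, (n + 1) / 2), arclength = 0,
      edgeDistance = Inf, outOfBounds = FALSE)
}
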