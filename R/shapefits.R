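## Least-squares fits of the idealized geometries to section masks.
## All fits work in the section frame: um coordinates with the origin at
## the image center pixel, h to the right and v up. Boundary pixel centers
## sit half a pixel inside the true edge on average, so a half-pixel
## rasterization correction is applied where it matters (circle radius,
## top/bottom boundary points, lobe ends).

## boundary pixel centers of a mask in um (section frame)
.boundaryPoints <- function(mask, pixelSize) {
  er <- EBImage::erode(EBImage::Image(mask * 1),
                       EBImage::makeBrush(3, shape = "box")) > 0.5
  ij <- which(mask & !er, arr.ind = TRUE)
  c0 <- (dim(mask) + 1) / 2
  cbind(h = (ij[, 1] - c0[1]) * pixelSize, v = (ij[, 2] - c0[2]) * pixelSize)
}

## distance from points to the boundary of their convex hull
.hullDepth <- function(pts) {
  hull <- grDevices::chull(pts)
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  n <- length(hull)
  dmin <- rep(Inf, nrow(pts))
  for (e in seq_len(n)) {
    x1 <- hx[e]; y1 <- hy[e]
    x2 <- hx[if (e == n) 1 else e + 1]; y2 <- hy[if (e == n) 1 else e + 1]
    ex <- x2 - x1; ey <- y2 - y1
    L2 <- ex^2 + ey^2
    if (L2 == 0) next
    t <- pmin(pmax(((pts[, 1] - x1) * ex + (pts[, 2] - y1) * ey) / L2, 0), 1)
    d <- sqrt((pts[, 1] - x1 - t * ex)^2 + (pts[, 2] - y1 - t * ey)^2)
    dmin <- pmin(dmin, d)
  }
  dmin
}

#' Fit a circle to the vessel boundary
#'
#' Collects vessel-mask boundary pixels, discards points lying deeper than
#' `erosionPx` pixels inside the convex hull of the boundary (the
#' unreliable bottom edge of a shadowed vessel retracts inward, so such
#' points sit well inside the hull), then fits a circle: algebraic
#' least-squares initialization refined by geometric (orthogonal-distance)
#' Gauss-Newton iteration. The fitted radius carries a half-pixel
#' rasterization correction.
#'
#' @param section a [VesselSection-class].
#' @param erosionPx convex-hull exclusion depth (pixels, default 3).
#' @param tol geometric refinement tolerance (um).
#' @return A [CircleFit-class].
#' @export
fitVesselCircle <- function(section, erosionPx = 3, tol = 1e-8) {
  p <- section@pixelSize
  if (sum(section@vessel) == 0) stop("empty vessel mask")
  pts <- .boundaryPoints(section@vessel, p)
  if (nrow(pts) < 8) stop("vessel mask has fewer than 8 boundary pixels")
  keep <- .hullDepth(pts) <= erosionPx * p
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 3) stop("fewer than 3 boundary points survive the hull exclusion")
  x <- pts[, 1]; y <- pts[, 2]
  ## Kasa algebraic fit
  sol <- tryCatch(qr.solve(cbind(2 * x, 2 * y, 1), x^2 + y^2),
                  error = function(e) stop("degenerate circle fit"))
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  for (it in 1:50) {
    dx <- x - cx; dy <- y - cy
    di <- sqrt(dx^2 + dy^2)
    f <- di - r
    J <- cbind(-dx / di, -dy / di, -1)
    step <- tryCatch(qr.solve(J, -f), error = function(e) rep(0, 3))
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
    if (max(abs(step)) < tol) break
  }
  new("CircleFit", center = c(cx, cy), r1 = r + p / 2)
}

#' Fit an elliptical annulus to the PVS by second central moments
#'
#' The ellipse shares the PVS mask's centroid and second central moments:
#' semi-axes are twice the square roots of the eigenvalues of the moment
#' matrix (the filled-ellipse identity), orientation is the leading
#' eigenvector. Offsets report the vessel center relative to the ellipse
#' center.
#'
#' @param section a [VesselSection-class].
#' @param vessel the section's [CircleFit-class].
#' @return An [EllipseAnnulusFit-class].
#' @export
fitEllipse <- function(section, vessel) {
  p <- section@pixelSize
  ij <- which(section@pvs, arr.ind = TRUE)
  if (nrow(ij) == 0) stop("empty PVS mask")
  c0 <- (dim(section@pvs) + 1) / 2
  x <- (ij[, 1] - c0[1]) * p; y <- (ij[, 2] - c0[2]) * p
  mx <- mean(x); my <- mean(y)
  ## second central moments of the pixelated region; p^2/12 is the moment
  ## of a single square pixel about its own center
  cxx <- mean((x - mx)^2) + p^2 / 12
  cyy <- mean((y - my)^2) + p^2 / 12
  cxy <- mean((x - mx) * (y - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  r2 <- 2 * sqrt(ev$values[1]); r3 <- 2 * sqrt(ev$values[2])
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  new("EllipseAnnulusFit", center = c(mx, my), r2 = r2, r3 = r3,
      angle = ang, oH = vessel@center[1] - mx, oV = vessel@center[2] - my,
      r1 = vessel@r1)
}

#' Fit the two-lobed polynomial geometry to the PVS
#'
#' One least-squares line is fitted to the top boundary (uppermost PVS
#' pixel per column, spanning both lobes), and one quadratic per side to
#' the bottom boundary (lowermost PVS pixel per column, columns outside the
#' vessel circle). Derived measures (per-side W, H1, H2, H3, and HC) follow
#' the conventions of [polynomialShape()]. A side with fewer than
#' `minColumns` boundary columns is marked absent; with both sides absent
#' the fit fails.
#'
#' @param section a [VesselSection-class].
#' @param vessel the section's [CircleFit-class].
#' @param minColumns minimum boundary columns per side.
#' @return A [PolynomialShape-class] (vessel-centered coefficients, with
#'   `center` recording the vessel center in the section frame).
#' @export
fitPolynomialShape <- function(section, vessel, minColumns = 3) {
  p <- section@pixelSize
  m <- section@pvs
  if (!any(m)) stop("empty PVS mask")
  c0 <- (dim(m) + 1) / 2
  cols <- which(colSums(m) > 0)  # columns are the h axis: work on rows
  ## per-column (h) extremes of the PVS mask
  hcols <- which(rowSums(m) > 0)
  topv <- vapply(hcols, function(i) max(which(m[i, ])), numeric(1))
  botv <- vapply(hcols, function(i) min(which(m[i, ])), numeric(1))
  ## vessel-centered um coordinates with half-pixel boundary correction
  hh <- (hcols - c0[1]) * p - vessel@center[1]
  top <- (topv - c0[2] + 0.5) * p - vessel@center[2]
  bot <- (botv - c0[2] - 0.5) * p - vessel@center[2]
  r1 <- vessel@r1
  topLine <- unname(coef(lm(top ~ hh)))[c(1, 2)]
  fitSide <- function(sel, sgn) {
    if (sum(sel) < minColumns) return(NULL)
    hs <- hh[sel]; bs <- bot[sel]
    qfit <- function(h, b) {
      q <- unname(coef(lm(b ~ h + I(h^2))))
      q[is.na(q)] <- 0
      q
    }
    q <- qfit(hs, bs)
    ## one robust pass: columns caught on the sliver above the vessel arc
    ## (or other stray pixels) are gross outliers against the first fit
    res <- bs - (q[1] + q[2] * hs + q[3] * hs^2)
    keep <- abs(res) <= pmax(3 * stats::mad(res), 2 * p)
    if (any(!keep) && sum(keep) >= minColumns) q <- qfit(hs[keep], bs[keep])
    w <- max(sgn * hs) + p / 2 - r1
    list(q = q, w = w)
  }
  ## a half-pixel margin keeps arc-sliver columns at |h| ~ R1 out of the
  ## lobe-bottom data
  right <- fitSide(hh > r1 + p / 2, 1)
  left <- fitSide(hh < -r1 - p / 2, -1)
  if (is.null(left) && is.null(right))
    stop("no PVS lobe with enough boundary columns on either side")
  .newPolynomialShape(r1, topLine,
                      bottomLeft = left$q, bottomRight = right$q,
                      wLeft = if (is.null(left)) NA_real_ else left$w,
                      wRight = if (is.null(right)) NA_real_ else right$w,
                      center = vessel@center)
}

#' Fit all idealized geometries to a section
#'
#' @param section a [VesselSection-class].
#' @param erosionPx convex-hull exclusion depth for the circle fit.
#' @return List with `circle`, `ellipse`, `spline`, `polynomial` fits plus
#'   the segmented areas (`vesselArea`, `pvsArea`, um^2) and segmented area
#'   ratio `K`.
#' @export
fitSection <- function(section, erosionPx = 3) {
  circ <- fitVesselCircle(section, erosionPx = erosionPx)
  ell <- tryCatch(fitEllipse(section, circ), error = function(e) NULL)
  poly <- tryCatch(fitPolynomialShape(section, circ), error = function(e) NULL)
  spl <- buildSplineShape(circ)
  p <- section@pixelSize
  va <- sum(section@vessel) * p^2
  pa <- sum(section@pvs) * p^2
  list(circle = circ, ellipse = ell, spline = spl, polynomial = poly,
       vesselArea = va, pvsArea = pa,
       K = if (va > 0) pa / va else NA_real_)
}
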