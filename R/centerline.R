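## Vessel centerline extraction and smoothing, and isotropic resampling of
## anisotropic volumes.

#' Resample a volume to isotropic voxels
#'
#' Linear interpolation along each axis onto a grid at the finest input
#' pitch (0.648 um for the standard acquisition). Masks are interpolated as
#' 0/1 fields and re-binarized at 0.5.
#'
#' @param volume a [VoxelStack-class] (intensity or mask).
#' @param binarize re-threshold interpolated masks at 0.5 (default). With
#'   `binarize = FALSE` a mask is returned as its soft 0..1 interpolant,
#'   which downstream oblique sampling can binarize once instead of twice
#'   (thin sheets survive better; see the methods vignette).
#' @return A [VoxelStack-class] with isotropic spacing.
#' @export
resampleIsotropic <- function(volume, binarize = TRUE) {
  sp <- voxelSpacing(volume)
  target <- min(sp)
  if (all(abs(sp - target) < 1e-12)) return(volume)
  arr <- voxelData(volume)
  isMask <- is.logical(arr) && binarize
  a <- arr * 1.0
  d <- dim(a)
  for (ax in 1:3) {
    if (abs(sp[ax] - target) < 1e-12) next
    d <- dim(a)
    n <- d[ax]
    pos <- seq(0, (n - 1) * sp[ax], by = target) / sp[ax] + 1
    i0 <- pmin(floor(pos), n - 1L)
    f <- pos - i0
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n)
    out <- m[i0, , drop = FALSE] * (1 - f) + m[i0 + 1L, , drop = FALSE] * f
    dim(out) <- c(length(pos), dim(ap)[2:3])
    a <- aperm(out, order(perm))
  }
  if (isMask) a <- a >= 0.5
  VoxelStack(a, rep(target, 3))
}

#' Extract a raw vessel centerline
#'
#' Estimates the axis of a single, gently curved, non-branching tube: along
#' the dominant extent axis of the mask, each transverse plane contributes
#' the centroid of its largest in-plane component. Points are returned in
#' um, ordered along the dominant axis. Small side stubs perturb the
#' centroids only in proportion to their area and are suppressed by the
#' quadratic smoothing of [smoothCenterline()].
#'
#' @param vessel a logical [VoxelStack-class] (one connected component).
#' @return n x 3 matrix of points (um).
#' @export
extractCenterline <- function(vessel) {
  m <- voxelData(vessel)
  sp <- voxelSpacing(vessel)
  if (!any(m)) stop("vessel mask is empty")
  idx <- which(m, arr.ind = TRUE)
  ext <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * sp
  ax <- which.max(ext[1:2])  # tube runs laterally; depth is never dominant
  perm <- c(ax, setdiff(1:3, ax))
  mp <- aperm(m, perm)
  d <- dim(mp)
  pts <- matrix(NA_real_, d[1], 3)
  for (i in seq_len(d[1])) {
    pl <- mp[i, , ]
    if (!any(pl)) next
    lab <- EBImage::bwlabel(pl)
    big <- which.max(tabulate(lab[lab > 0]))
    ij <- which(lab == big, arr.ind = TRUE)
    pts[i, ] <- c(i, mean(ij[, 1]), mean(ij[, 2]))
  }
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  ## back to original axis order and um units
  out <- matrix(NA_real_, nrow(pts), 3)
  out[, perm] <- pts
  sweep(out - 1, 2, sp, `*`)
}

#' Smooth a centerline and build section frames
#'
#' Fits second-order polynomials to the raw points in the transverse plane
#' and in the axial plane (the parameterizing axis is the one with the
#' larger lateral extent), resamples the fitted curve at uniform arclength
#' spacing, and constructs an orthonormal frame per station: the tangent
#' from the fit derivatives, `normalU` as the in-plane perpendicular of the
#' transverse fit, and `normalV = tangent x normalU` oriented toward
#' decreasing cortical depth ("up").
#'
#' @param points n x 3 matrix (um), n >= 3.
#' @param spacing arclength spacing of the output stations (um).
#' @return A [Centerline-class].
#' @export
smoothCenterline <- function(points, spacing = 0.8) {
  stopifnot(nrow(points) >= 3)
  ext <- apply(points[, 1:2, drop = FALSE], 2, function(v) diff(range(v)))
  ax <- which.max(ext)
  oth <- 3 - ax
  t0 <- points[, ax]
  fitT <- lm(points[, oth] ~ t0 + I(t0^2))
  fitA <- lm(points[, 3] ~ t0 + I(t0^2))
  cT <- coef(fitT); cA <- coef(fitA)
  cT[is.na(cT)] <- 0; cA[is.na(cA)] <- 0
  rng <- range(t0)
  tt <- seq(rng[1], rng[2], length.out = 4001)
  dT <- cT[2] + 2 * cT[3] * tt
  dA <- cA[2] + 2 * cA[3] * tt
  ds <- sqrt(1 + dT^2 + dA^2)
  s <- c(0, cumsum((ds[-1] + ds[-length(ds)]) / 2 * diff(tt)))
  stations <- seq(0, max(s), by = spacing)
  ts <- approx(s, tt, stations)$y
  evalC <- function(t) {
    p <- matrix(0, length(t), 3)
    p[, ax] <- t
    p[, oth] <- cT[1] + cT[2] * t + cT[3] * t^2
    p[, 3] <- cA[1] + cA[2] * t + cA[3] * t^2
    p
  }
  P <- evalC(ts)
  dT <- cT[2] + 2 * cT[3] * ts
  dA <- cA[2] + 2 * cA[3] * ts
  Tg <- matrix(0, length(ts), 3)
  Tg[, ax] <- 1; Tg[, oth] <- dT; Tg[, 3] <- dA
  Tg <- Tg / sqrt(rowSums(Tg^2))
  U <- matrix(0, length(ts), 3)
  nU <- sqrt(1 + dT^2)
  U[, ax] <- -dT / nU; U[, oth] <- 1 / nU
  V <- cbind(Tg[, 2] * U[, 3] - Tg[, 3] * U[, 2],
             Tg[, 3] * U[, 1] - Tg[, 1] * U[, 3],
             Tg[, 1] * U[, 2] - Tg[, 2] * U[, 1])
  V <- V / sqrt(rowSums(V^2))
  flip <- V[, 3] > 0
  V[flip, ] <- -V[flip, ]
  ## keep (U, V) consistent as a screen frame: h to the right, v up
  U <- cbind(Tg[, 2] * V[, 3] - Tg[, 3] * V[, 2],
             Tg[, 3] * V[, 1] - Tg[, 1] * V[, 3],
             Tg[, 1] * V[, 2] - Tg[, 2] * V[, 1])
  U <- U / sqrt(rowSums(U^2))
  new("Centerline", points = P, tangents = Tg, normalU = U, normalV = V,
      arclength = stations)
}
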