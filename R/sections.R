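## Sampling of centerline-normal cross sections and section bookkeeping.

#' Extract a centerline-normal cross section
#'
#' Samples the vessel and PVS masks on the plane spanned by the station's
#' `(normalU, normalV)` frame through the centerline point, at the isotropic
#' voxel pitch, then recenters the image on the vessel centroid so the
#' vessel center sits at the central pixel. Masks are sampled trilinearly
#' and re-binarized at 0.5. Sections whose sampling plane leaves the volume
#' are flagged `outOfBounds` for the edge-exclusion rule.
#'
#' @param vessel,pvs logical [VoxelStack-class]s on the same isotropic grid.
#' @param cl a [Centerline-class].
#' @param index station index.
#' @param halfWidth half-width of the section image (um).
#' @param pixelSize section pixel pitch (um); defaults to the voxel pitch.
#' @return A [VesselSection-class].
#' @export
extractNormalSection <- function(vessel, pvs, cl, index, halfWidth = 45,
                                 pixelSize = NULL) {
  sp <- voxelSpacing(vessel)
  stopifnot(max(abs(sp - sp[1])) < 1e-9)  # isotropic input required
  if (index < 1 || index > length(cl)) stop("station index out of range")
  if (is.null(pixelSize)) pixelSize <- sp[1]
  halfWidth <- pixelSize * ceiling(halfWidth / pixelSize)  # symmetric grid
  mv <- voxelData(vessel) * 1.0
  mp <- voxelData(pvs) * 1.0
  d <- dim(mv)
  u <- cl@normalU[index, ]; v <- cl@normalV[index, ]
  ctr <- cl@points[index, ]
  off <- seq(-halfWidth, halfWidth, by = pixelSize)
  n <- length(off)
  A <- matrix(off, n, n); B <- matrix(off, n, n, byrow = TRUE)
  sample2 <- function(center) {
    px <- center[1] + as.numeric(A) * u[1] + as.numeric(B) * v[1]
    py <- center[2] + as.numeric(A) * u[2] + as.numeric(B) * v[2]
    pz <- center[3] + as.numeric(A) * u[3] + as.numeric(B) * v[3]
    vox <- cbind(px / sp[1], py / sp[2], pz / sp[3]) + 1
    ## only lateral exits matter: sampling above the surface or below the
    ## deepest plane hits empty space and is filled with background
    oob <- any(vox[, 1] < 1) || any(vox[, 1] > d[1]) ||
      any(vox[, 2] < 1) || any(vox[, 2] > d[2])
    list(vessel = matrix(trilinear(mv, vox) >= 0.5, n, n),
         pvs = matrix(trilinear(mp, vox) >= 0.5, n, n),
         oob = oob)
  }
  sm <- sample2(ctr)
  ## recenter on the vessel centroid (two passes)
  for (it in 1:2) {
    if (!any(sm$vessel)) break
    ij <- which(sm$vessel, arr.ind = TRUE)
    mid <- (n + 1) / 2
    dh <- (mean(ij[, 1]) - mid) * pixelSize
    dv <- (mean(ij[, 2]) - mid) * pixelSize
    if (abs(dh) < pixelSize / 4 && abs(dv) < pixelSize / 4) break
    ctr <- ctr + dh * u + dv * v
    sm <- sample2(ctr)
  }
  vmask <- sm$vessel; pmask <- sm$pvs & !sm$vessel
  edist <- min(ctr[1], (d[1] - 1) * sp[1] - ctr[1],
               ctr[2], (d[2] - 1) * sp[2] - ctr[2])
  new("VesselSection", vessel = vmask, pvs = pmask, pixelSize = pixelSize,
      center = c((n + 1) / 2, (n + 1) / 2), arclength = cl@arclength[index],
      edgeDistance = edist, outOfBounds = sm$oob)
}

#' Extract sections at every centerline station
#'
#' @param vessel,pvs isotropic mask [VoxelStack-class]s.
#' @param cl a [Centerline-class].
#' @param halfWidth section half-width (um).
#' @param stride keep every `stride`-th station (1 = all).
#' @return List of [VesselSection-class].
#' @export
extractSections <- function(vessel, pvs, cl, halfWidth = 45, stride = 1L) {
  idx <- seq(1L, length(cl), by = stride)
  lapply(idx, function(i)
    extractNormalSection(vessel, pvs, cl, i, halfWidth = halfWidth))
}

#' Horizontal PVS width of a section (um)
#'
#' @param section a [VesselSection-class].
#' @return Width of the PVS footprint along the horizontal axis (um); 0
#'   when the section has no PVS pixels.
#' @export
sectionPvsWidth <- function(section) {
  if (!any(section@pvs)) return(0)
  cols <- range(which(rowSums(section@pvs) > 0))
  (cols[2] - cols[1] + 1) * section@pixelSize
}

#' Drop sections too close to the acquisition edge
#'
#' Removes sections flagged out-of-bounds and those whose vessel center
#' lies closer to the nearest lateral face of the acquisition volume than
#' the median PVS width divided by 2.5 (strict inequality: a section at
#' exactly the cutoff is retained).
#'
#' @param sections list of [VesselSection-class].
#' @return Filtered list.
#' @export
excludeEdgeSections <- function(sections) {
  widths <- vapply(sections, sectionPvsWidth, numeric(1))
  medw <- median(widths[widths > 0])
  if (!is.finite(medw)) stop("no PVS pixels in any section; cannot compute median width")
  keep <- vapply(sections, function(s)
    !s@outOfBounds && !(s@edgeDistance < medw / 2.5), logical(1))
  out <- sections[keep]
  if (!length(out)) stop("all sections excluded by the edge rule")
  out
}

#' Pixel-wise mean of section images
#'
#' Averages aligned section masks (or intensity images) along the
#' centerline, producing the representative cross-section image.
#'
#' @param sections list of [VesselSection-class] or of numeric matrices.
#' @param channel `"pvs"` or `"vessel"` when sections are
#'   [VesselSection-class] objects.
#' @return Numeric matrix of per-pixel means.
#' @export
averageSections <- function(sections, channel = c("pvs", "vessel")) {
  if (!length(sections)) stop("no sections to average")
  channel <- match.arg(channel)
  mats <- lapply(sections, function(s)
    if (is.matrix(s)) s * 1.0 else slot(s, channel) * 1.0)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("sections must share a common shape")
  Reduce(`+`, mats) / length(mats)
}
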