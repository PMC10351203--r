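## Depth-varying threshold segmentation of vessel and PVS channels, mask
## cleanup, overlap resolution, and validation metrics.

#' Depth-varying intensity threshold
#'
#' One threshold per depth plane. `values` may contain NA where a plane
#' provided no evidence (e.g. no detectable edges); [refineThreshold()]
#' fills them from the three-piece model and guarantees a non-increasing
#' profile.
#'
#' @slot values numeric vector, one entry per depth.
#' @slot model list describing the fitted three-piece profile (high level,
#'   low level, ramp start/end depth indices), empty for raw thresholds.
#' @export
setClass("DepthThreshold",
  representation(values = "numeric", model = "list"))

setMethod("show", "DepthThreshold", function(object) {
  cat(sprintf("DepthThreshold: %d depths, %d missing%s\n",
              length(object@values), sum(is.na(object@values)),
              if (length(object@model))
                sprintf("; model %.1f -> %.1f over depths %d..%d",
                        object@model$high, object@model$low,
                        object@model$rampStart, object@model$rampEnd)
              else ""))
})

#' @describeIn DepthThreshold-class threshold values per depth
#' @param x a DepthThreshold
#' @export
setGeneric("thresholdValues", function(x) standardGeneric("thresholdValues"))
#' @export
setMethod("thresholdValues", "DepthThreshold", function(x) x@values)

#' Edge Finder depth-varying threshold
#'
#' Smooths the stack with a 3D Gaussian (sigma 2 voxels), detects edge
#' pixels on every depth plane as the gradient-magnitude ridge (pixels
#' whose gradient magnitude exceeds the per-plane Otsu level of gradient
#' magnitude), and sets the plane threshold to the median smoothed
#' intensity over the edge pixels. Planes without detectable edges get NA,
#' to be filled by [refineThreshold()].
#'
#' @param stack an intensity [VoxelStack-class].
#' @param smoothSigma Gaussian sigma in voxels (default 2).
#' @return A [DepthThreshold-class] with raw (possibly NA) values.
#' @export
edgeFinderThreshold <- function(stack, smoothSigma = 2) {
  arr <- voxelData(stack)
  d <- dim(arr)
  if (d[3] < 1) stop("stack needs at least one depth plane")
  sm <- gaussBlur3d(arr, rep(smoothSigma, 3))
  grads <- lapply(seq_len(d[3]), function(k) {
    pl <- sm[, , k]
    gx <- (pl[c(2:d[1], d[1]), ] - pl[c(1, 1:(d[1] - 1)), ]) / 2
    gy <- (pl[, c(2:d[2], d[2])] - pl[, c(1, 1:(d[2] - 1))]) / 2
    sqrt(gx^2 + gy^2)
  })
  ## planes without real structure only carry numerical-noise gradients;
  ## treat them as edge-less so the three-piece refinement fills them in
  gmax <- max(vapply(grads, max, numeric(1)))
  scale <- max(abs(sm))
  vals <- vapply(seq_len(d[3]), function(k) {
    gm <- grads[[k]]
    if (max(gm) <= max(0.05 * gmax, 1e-9 * scale)) return(NA_real_)
    lev <- otsuLevel(gm)
    if (is.na(lev)) return(NA_real_)
    edge <- gm > lev
    if (!any(edge)) return(NA_real_)
    median(sm[, , k][edge])
  }, numeric(1))
  new("DepthThreshold", values = vals, model = list())
}

#' Mean + Standard Deviation depth-varying threshold
#'
#' Per depth, the threshold is the plane mean plus the plane (population)
#' standard deviation; thresholds shallower than the depth of the maximum
#' are then clamped to that maximum.
#'
#' @param stack an intensity [VoxelStack-class].
#' @return A [DepthThreshold-class].
#' @export
meanStdThreshold <- function(stack) {
  arr <- voxelData(stack)
  d <- dim(arr)
  vals <- vapply(seq_len(d[3]), function(k) {
    pl <- as.numeric(arr[, , k])
    mean(pl) + sqrt(mean((pl - mean(pl))^2))
  }, numeric(1))
  im <- which.max(vals)
  if (im > 1) vals[seq_len(im - 1)] <- vals[im]
  new("DepthThreshold", values = vals, model = list())
}

#' Per-depth Otsu threshold (comparator)
#'
#' Plain per-plane Otsu level, provided for comparison with the Edge Finder
#' and Mean + SD profiles; it tends to over-segment low-signal planes.
#'
#' @param stack an intensity [VoxelStack-class].
#' @return A [DepthThreshold-class].
#' @export
otsuThreshold <- function(stack) {
  arr <- voxelData(stack)
  vals <- vapply(seq_len(dim(arr)[3]), function(k)
    otsuLevel(as.numeric(arr[, , k])), numeric(1))
  new("DepthThreshold", values = vals, model = list())
}

## least-squares three-piece profile (high constant, linear ramp, low
## constant) via exhaustive search over breakpoint pairs
.fitThreePiece <- function(z, y, depth) {
  best <- NULL
  ## breakpoints are confined to the span of usable planes so the two
  ## constant levels are always anchored by data
  for (a in min(z):(max(z) - 1)) {
    for (b in (a + 1):max(z)) {
      w <- ifelse(z <= a, 1, ifelse(z >= b, 0, (b - z) / (b - a)))
      ## y ~ low + (high - low) * w ; closed-form LS in (low, high)
      sw <- sum(w); sww <- sum(w * w); n <- length(z)
      det <- n * sww - sw * sw
      if (det < 1e-12) next
      sy <- sum(y); syw <- sum(y * w)
      low <- (sww * sy - sw * syw) / det
      high <- low + (n * syw - sw * sy) / det
      if (high < low) { low <- high <- mean(y) }
      r <- sum((y - (low + (high - low) * w))^2)
      if (is.null(best) || r < best$r)
        best <- list(high = high, low = low, rampStart = a, rampEnd = b, r = r)
    }
  }
  best
}

#' Refine a raw depth threshold to the three-piece model
#'
#' Fits, by least squares over all breakpoint pairs, a profile that is
#' constant at shallow depths, decreases linearly, and is constant at deep
#' depths (`high >= low` enforced), then fills missing entries from the
#' model. The result is non-increasing with depth by construction.
#'
#' @param raw a [DepthThreshold-class] with >= 4 non-missing values.
#' @return A refined [DepthThreshold-class] with its `model` populated.
#' @export
refineThreshold <- function(raw) {
  y0 <- thresholdValues(raw)
  depth <- length(y0)
  keep <- which(!is.na(y0))
  if (length(keep) < 4) stop("need at least 4 usable threshold values")
  best <- .fitThreePiece(keep, y0[keep], depth)
  z <- seq_len(depth)
  w <- ifelse(z <= best$rampStart, 1,
              ifelse(z >= best$rampEnd, 0,
                     (best$rampEnd - z) / (best$rampEnd - best$rampStart)))
  vals <- best$low + (best$high - best$low) * w
  new("DepthThreshold", values = vals,
      model = list(high = best$high, low = best$low,
                   rampStart = best$rampStart, rampEnd = best$rampEnd,
                   rss = best$r))
}

#' Apply a depth threshold to an intensity stack
#'
#' A voxel is classified as foreground when its intensity strictly exceeds
#' the threshold of its depth plane.
#'
#' @param stack an intensity [VoxelStack-class].
#' @param thr a [DepthThreshold-class] of matching depth.
#' @return A logical mask [VoxelStack-class].
#' @export
applyThreshold <- function(stack, thr) {
  arr <- voxelData(stack)
  v <- thresholdValues(thr)
  if (length(v) != dim(arr)[3]) stop("threshold/stack depth mismatch")
  m <- arr > rep(v, each = dim(arr)[1] * dim(arr)[2])
  dim(m) <- dim(arr)
  VoxelStack(m, voxelSpacing(stack))
}

#' Clean a segmentation mask
#'
#' Removes per-depth 2D components smaller than `minRegionPx`, keeps the
#' largest 3D connected component (vessel) or the two largest (PVS), then
#' fills enclosed holes in every depth plane.
#'
#' @param mask a logical [VoxelStack-class].
#' @param role `"vessel"` or `"pvs"`; controls how many 3D components
#'   survive.
#' @param minRegionPx small-region cutoff in pixels, within 5..10.
#' @return The cleaned mask.
#' @export
cleanMask <- function(mask, role = c("vessel", "pvs"), minRegionPx = 5) {
  role <- match.arg(role)
  stopifnot(minRegionPx >= 5, minRegionPx <= 10)
  m <- voxelData(mask)
  d <- dim(m)
  for (k in seq_len(d[3])) {
    lk <- EBImage::bwlabel(m[, , k])
    if (max(lk) == 0) next
    sz <- tabulate(lk[lk > 0])
    small <- which(sz < minRegionPx)
    if (length(small)) {
      pk <- m[, , k]
      pk[lk %in% small] <- FALSE
      m[, , k] <- pk
    }
  }
  lab <- label3d(m)
  ncomp <- max(lab)
  if (ncomp == 0) {
    warning("mask is empty after cleaning")
    return(VoxelStack(m, voxelSpacing(mask)))
  }
  sz <- tabulate(lab[lab > 0])
  keep <- order(sz, decreasing = TRUE)[seq_len(min(if (role == "vessel") 1L else 2L,
                                                   ncomp))]
  m <- array(lab %in% keep, d)
  for (k in seq_len(d[3]))
    m[, , k] <- EBImage::fillHull(m[, , k]) > 0
  VoxelStack(m, voxelSpacing(mask))
}

#' Remove vessel/PVS segmentation overlap
#'
#' Voxels claimed by both masks are removed from the non-priority mask, so
#' the outputs are disjoint.
#'
#' @param vessel,pvs logical [VoxelStack-class]s of identical dimensions.
#' @param priority which mask keeps contested voxels.
#' @return List with disjoint `vessel` and `pvs` masks.
#' @export
resolveOverlap <- function(vessel, pvs, priority = c("vessel", "pvs")) {
  priority <- match.arg(priority)
  mv <- voxelData(vessel); mp <- voxelData(pvs)
  stopifnot(identical(dim(mv), dim(mp)))
  both <- mv & mp
  if (priority == "vessel") mp <- mp & !both else mv <- mv & !both
  list(vessel = VoxelStack(mv, voxelSpacing(vessel)),
       pvs = VoxelStack(mp, voxelSpacing(pvs)))
}

#' Intersection-over-union of two 2D masks
#'
#' The validation overlap score: `|A intersect B| / |A union B|`. A
#' segmentation is conventionally accepted when the score reaches 0.70.
#'
#' @param mask2d,slice3d logical matrices of identical shape.
#' @return Scalar in [0, 1].
#' @export
overlapFraction <- function(mask2d, slice3d) {
  stopifnot(identical(dim(mask2d), dim(slice3d)))
  u <- sum(mask2d | slice3d)
  if (u == 0) stop("both masks are empty; overlap undefined")
  sum(mask2d & slice3d) / u
}

#' 3D Dice coefficient
#'
#' `DC = 2 |A intersect B| / (|A| + |B|)`.
#'
#' @param a,b logical arrays or mask [VoxelStack-class]s of identical
#'   dimensions.
#' @return Scalar in [0, 1].
#' @export
dice3d <- function(a, b) {
  if (is(a, "VoxelStack")) a <- voxelData(a)
  if (is(b, "VoxelStack")) b <- voxelData(b)
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) stop("both masks are empty; Dice undefined")
  2 * sum(a & b) / s
}

#' Segment one channel of a stack
#'
#' Convenience wrapper: compute the depth-varying threshold with the chosen
#' method, refine it (Edge Finder path), apply it, and clean the mask.
#'
#' @param stack intensity [VoxelStack-class].
#' @param role `"vessel"` or `"pvs"`.
#' @param method threshold method.
#' @param minRegionPx small-region cutoff (pixels).
#' @return List with the `mask` and the `threshold` used.
#' @export
segmentChannel <- function(stack, role = c("vessel", "pvs"),
                           method = c("edge", "meanstd", "otsu"),
                           minRegionPx = 5) {
  role <- match.arg(role)
  method <- match.arg(method)
  thr <- switch(method,
                edge = refineThreshold(edgeFinderThreshold(stack)),
                meanstd = meanStdThreshold(stack),
                otsu = otsuThreshold(stack))
  mask <- cleanMask(applyThreshold(stack, thr), role = role,
                    minRegionPx = minRegionPx)
  list(mask = mask, threshold = thr)
}

## ---- 2D-to-3D registration -------------------------------------------------

## rotate a 2D image about its center by `angle` radians (bilinear)
.rotate2d <- function(img, angle) {
  d <- dim(img)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  gx <- matrix(seq_len(d[1]), d[1], d[2]) - cx
  gy <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cy
  ca <- cos(angle); sa <- sin(angle)
  sx <- ca * gx - sa * gy + cx
  sy <- sa * gx + ca * gy + cy
  v <- trilinear(array(img, c(d, 1)), cbind(as.numeric(sx), as.numeric(sy), 1),
                 fill = mean(img))
  matrix(v, d[1], d[2])
}

## FFT cross-correlation of zero-mean images; returns best integer shift of
## b relative to a within +/- maxShift and the normalized score
.bestShift <- function(a, b, maxShift) {
  d <- dim(a)
  a0 <- a - mean(a); b0 <- b - mean(b)
  fa <- fft(a0); fb <- fft(b0)
  cc <- Re(fft(fa * Conj(fb), inverse = TRUE)) / length(a0)
  sx <- c(0:(d[1] - 1)); sx[sx > d[1] / 2] <- sx[sx > d[1] / 2] - d[1]
  sy <- c(0:(d[2] - 1)); sy[sy > d[2] / 2] <- sy[sy > d[2] / 2] - d[2]
  ok <- outer(abs(sx) <= maxShift, abs(sy) <= maxShift)
  cc[!ok] <- -Inf
  i <- which.max(cc)
  ij <- arrayInd(i, d)
  score <- cc[i] / (sqrt(sum(a0^2)) * sqrt(sum(b0^2)))
  list(shift = c(sx[ij[1]], sy[ij[2]]), score = score)
}

#' Register a high-SNR 2D image to a 3D stack
#'
#' Finds the depth plane and rigid in-plane transform (rotation about the
#' image center plus translation) that maximize the normalized
#' cross-correlation between the reference image and the stack plane.
#' Rotation is searched on a coarse grid and refined continuously;
#' translation is recovered by FFT cross-correlation.
#'
#' @param ref2d 2D numeric matrix with the same pixel size as the stack
#'   planes.
#' @param stack intensity [VoxelStack-class].
#' @param maxAngle rotation search half-range (degrees).
#' @param maxShift translation search half-range (pixels).
#' @param minScore similarity floor below which registration fails.
#' @return List: `depth` (the best-matching plane index), `angle` and
#'   `shift` (the rotation in radians and translation in pixels to apply
#'   to `ref2d` to align it with that plane), and the similarity `score`.
#' @export
register2dTo3d <- function(ref2d, stack, maxAngle = 10, maxShift = 32,
                           minScore = 0.3) {
  arr <- voxelData(stack)
  d <- dim(arr)
  stopifnot(identical(dim(ref2d), d[1:2]))
  angles <- seq(-maxAngle, maxAngle, by = 1) * pi / 180
  rots <- lapply(angles, function(a) .rotate2d(ref2d, a))
  best <- list(score = -Inf)
  for (k in seq_len(d[3])) {
    pl <- arr[, , k]
    if (sd(pl) == 0) next
    ## coarse angle grid at this depth
    sc <- vapply(rots, function(r) .bestShift(pl, r, maxShift)$score,
                 numeric(1))
    ib <- which.max(sc)
    if (sc[ib] > best$score)
      best <- list(score = sc[ib], depth = k, angle = angles[ib])
  }
  if (!is.finite(best$score)) stop("registration failed: stack has no contrast")
  pl <- arr[, , best$depth]
  opt <- optimise(function(a) .bestShift(pl, .rotate2d(ref2d, a), maxShift)$score,
                  interval = best$angle + c(-1, 1) * 1.5 * pi / 180,
                  maximum = TRUE)
  fin <- .bestShift(pl, .rotate2d(ref2d, opt$maximum), maxShift)
  if (fin$score < minScore)
    stop(sprintf("registration failed: best similarity %.3f below floor %.3f",
                 fin$score, minScore))
  list(depth = best$depth, angle = opt$maximum, shift = fin$shift,
       score = fin$score)
}
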