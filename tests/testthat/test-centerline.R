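# a true circular cylinder whose axis runs along x with slope `tilt` in z:
# voxels within distance r of the 3D axis line
cylinderStack <- function(r = 10, len = 60, n = 28, tilt = 0,
                          spacing = c(1, 1, 1), stub = FALSE) {
  cy <- (n + 1) / 2
  g <- expand.grid(x = seq_len(len), y = seq_len(n), z = seq_len(n))
  t <- c(1, 0, tilt) / sqrt(1 + tilt^2)
  dx <- g$x - len / 2; dy <- g$y - cy; dz <- g$z - cy - tilt * (g$x - len / 2)
  dz <- g$z - (cy + tilt * (g$x - len / 2))
  proj <- dx * t[1] + dy * t[2] + (g$z - cy) * t[3]
  d2 <- dx^2 + dy^2 + (g$z - cy)^2 - proj^2
  arr <- array(FALSE, c(len, n, n))
  arr[as.matrix(g[d2 <= r^2, ])] <- TRUE
  if (stub) arr[28:32, round(cy) + seq(r, r + 4), round(cy)] <- TRUE
  VoxelStack(arr, spacing)
}

test_that("isotropic resampling preserves geometry", {
  iso <- VoxelStack(array(runif(4 * 4 * 4), c(4, 4, 4)), c(1, 1, 1))
  expect_identical(voxelData(resampleIsotropic(iso)), voxelData(iso))

  ## solid sphere rendered on an anisotropic grid keeps its volume
  sp <- c(0.648, 0.648, 1)
  n <- c(40, 40, 26)
  ctr <- (n - 1) / 2 * sp
  g <- expand.grid(i = 1:n[1], j = 1:n[2], k = 1:n[3])
  r2 <- ((g$i - 1) * sp[1] - ctr[1])^2 + ((g$j - 1) * sp[2] - ctr[2])^2 +
    ((g$k - 1) * sp[3] - ctr[3])^2
  sph <- array(r2 <= 10^2, n)
  out <- resampleIsotropic(VoxelStack(sph, sp))
  v0 <- sum(sph) * prod(sp)
  v1 <- sum(voxelData(out)) * prod(voxelSpacing(out))
  expect_lt(abs(v1 - v0) / v0, 0.02)

  ## a single voxel survives resampling
  one <- array(FALSE, c(9, 9, 9)); one[5, 5, 5] <- TRUE
  expect_gt(sum(voxelData(resampleIsotropic(VoxelStack(one, sp)))), 0)
})

test_that("centerline extraction tracks the tube axis", {
  cyl <- cylinderStack()
  pts <- extractCenterline(cyl)
  expect_true(all(abs(pts[, 2] - 13.5) <= 1))
  expect_true(all(abs(pts[, 3] - 13.5) <= 1))
  expect_error(extractCenterline(VoxelStack(array(FALSE, c(4, 4, 4)),
                                            c(1, 1, 1))), "empty")

  ## curved synthetic tube: within 1.5 voxels of the true axis
  g <- smallGeometry()
  isoV <- resampleIsotropic(cleanStack()$vesselMask)
  pts2 <- extractCenterline(isoV)
  yTrue <- g@coefY[1] + g@coefY[2] * pts2[, 1] + g@coefY[3] * pts2[, 1]^2
  zTrue <- g@coefZ[1] + g@coefZ[2] * pts2[, 1] + g@coefZ[3] * pts2[, 1]^2
  err <- sqrt((pts2[, 2] - yTrue)^2 + (pts2[, 3] - zTrue)^2)
  expect_lt(max(err) / 0.648, 1.5)

  ## a small side stub barely disturbs the smoothed centerline
  stubbed <- smoothCenterline(extractCenterline(cylinderStack(stub = TRUE)))
  expect_lt(max(abs(stubbed@points[, 2] - 13.5)), 1.5)
})

test_that("centerline smoothing produces orthonormal, up-oriented frames", {
  ## collinear points: constant tangent along the line
  line <- cbind(seq(0, 50, by = 1), seq(0, 25, by = 0.5), rep(3, 51))
  cl <- smoothCenterline(line)
  dirs <- cl@tangents
  expect_lt(max(abs(sweep(dirs, 2, dirs[1, ]))), 1e-9)
  expect_equal(unname(dirs[1, ]), c(2, 1, 0) / sqrt(5), tolerance = 1e-9)

  ## parabola y = x^2/100: tangent at x = 0 is +x
  x <- seq(-40, 40, by = 1)
  par <- cbind(x, x^2 / 100, rep(0, length(x)))
  clp <- smoothCenterline(par)
  i0 <- which.min(abs(clp@points[, 1]))
  expect_equal(unname(clp@tangents[i0, ]), c(1, 0, 0), tolerance = 1e-2)

  ## noisy parabola: quadratic coefficient recovered within 10%
  set.seed(3)
  noisy <- par + cbind(0, rnorm(length(x), sd = 0.5), rnorm(length(x), sd = 0.5))
  cln <- smoothCenterline(noisy)
  p <- cln@points
  fit <- lm(p[, 2] ~ p[, 1] + I(p[, 1]^2))
  expect_lt(abs(coef(fit)[3] - 0.01) / 0.01, 0.1)

  ## station spacing ~0.8 um; frames orthonormal; v points up (-z)
  expect_equal(mean(diff(cl@arclength)), 0.8, tolerance = 1e-6)
  expect_true(all(cl@normalV[, 3] <= 0))
  expect_lt(max(abs(rowSums(cl@tangents * cl@normalU))), 1e-9)
})

test_that("normal sections of cylinders are circles", {
  cyl <- cylinderStack(r = 10, len = 60, n = 31)
  cl <- smoothCenterline(extractCenterline(cyl))
  sec <- extractNormalSection(cyl, cyl, cl, round(length(cl) / 2),
                              halfWidth = 14)
  f <- fitVesselCircle(sec)
  expect_lt(abs(f@r1 - 10), 1)

  ## tilted tube sampled on axis-normal planes: still a disk of the true
  ## radius, whereas an axis-aligned slice would be an ellipse with
  ## major axis r / cos(tilt)
  tilted <- cylinderStack(r = 10, len = 50, n = 55, tilt = 0.6)
  clt <- smoothCenterline(extractCenterline(tilted))
  sect <- extractNormalSection(tilted, tilted, clt, round(length(clt) / 2),
                               halfWidth = 14)
  ft <- fitVesselCircle(sect)
  expect_lt(abs(ft@r1 - 10), 1)
  ## the normal section is a disk of the true radius, whereas an
  ## axis-aligned slice of the same tube is an ellipse elongated by
  ## 1/cos(tilt): its major extent exceeds anything seen in the section
  extents <- c(diff(range(which(rowSums(sect@vessel) > 0))),
               diff(range(which(colSums(sect@vessel) > 0))))
  axisSlice <- voxelData(tilted)[25, , ]
  axExt <- c(diff(range(which(rowSums(axisSlice) > 0))),
             diff(range(which(colSums(axisSlice) > 0))))
  expect_gte(max(axExt) - max(extents), 1.5)

  ## vessel centroid is recentered onto the image center
  ij <- which(sect@vessel, arr.ind = TRUE)
  expect_lt(max(abs(colMeans(ij) - sect@center)), 1)
})

test_that("synthetic PVS sections match the analytic shape area", {
  secs <- cleanSections()
  mid <- secs[[round(length(secs) / 2)]]
  truth <- groundTruthSections(smallGeometry(), mid@arclength)[[1]]
  a <- sum(mid@pvs) * mid@pixelSize^2
  expect_lt(abs(a - shapeArea(truth)) / shapeArea(truth), 0.03)
})

test_that("edge-exclusion rule drops exactly the prescribed sections", {
  mk <- function(edist, oob = FALSE, w = 20) {
    pv <- matrix(FALSE, 31, 31)
    pv[16 + seq(-round(w / 2), round(w / 2)), 14:18] <- TRUE
    new("VesselSection", vessel = matrix(FALSE, 31, 31), pvs = pv,
        pixelSize = 1, center = c(16, 16), arclength = 0,
        edgeDistance = edist, outOfBounds = oob)
  }
  far <- lapply(c(50, 60, 70), mk)
  expect_length(excludeEdgeSections(far), 3)

  ## median width is 21; the cutoff is 21/2.5 = 8.4, strict inequality
  mixed <- list(mk(8.4), mk(8.39), mk(50), mk(50, oob = TRUE))
  kept <- excludeEdgeSections(mixed)
  expect_length(kept, 2)
  expect_equal(vapply(kept, slot, numeric(1), "edgeDistance"), c(8.4, 50))

  ## hand-applied rule on the synthetic stack sections
  secs0 <- cleanSections()
  widths <- vapply(secs0, sectionPvsWidth, numeric(1))
  cutoff <- median(widths[widths > 0]) / 2.5
  byHand <- sum(vapply(secs0, function(s)
    !s@outOfBounds && !(s@edgeDistance < cutoff), logical(1)))
  expect_length(excludeEdgeSections(secs0), byHand)
})

test_that("section averaging is the pixel-wise mean", {
  secs <- cleanSections()
  same <- secs[c(10, 10, 10)]
  avg <- averageSections(same, "pvs")
  expect_equal(avg, secs[[10]]@pvs * 1.0)

  a <- matrix(0, 4, 4); a[1, 1] <- 1
  b <- matrix(0, 4, 4); b[4, 4] <- 1
  m <- averageSections(list(a, b))
  expect_equal(m[1, 1], 0.5); expect_equal(m[4, 4], 0.5)
  expect_error(averageSections(list()), "no sections")

  ## constant-profile tube: thresholding the mean reproduces one section
  avgAll <- averageSections(secs, "vessel")
  mid <- secs[[round(length(secs) / 2)]]
  expect_gt(dice3d(array(avgAll >= 0.5, c(dim(avgAll), 1)),
                   array(mid@vessel, c(dim(mid@vessel), 1))), 0.95)
})
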