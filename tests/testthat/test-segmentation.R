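test_that("mean + standard deviation threshold follows its definition", {
  mk <- function(planes) VoxelStack(array(unlist(planes),
                                          c(dim(planes[[1]]), length(planes))))
  ## constant plane: sd = 0, threshold = the constant
  s <- mk(list(matrix(7, 8, 8)))
  expect_equal(thresholdValues(meanStdThreshold(s)), 7)
  ## half zeros, half tens: mean 5, population sd 5, threshold 10
  pl <- matrix(c(rep(0, 32), rep(10, 32)), 8, 8)
  expect_equal(thresholdValues(meanStdThreshold(mk(list(pl)))), 10)
  ## shallow planes clamp to the maximum threshold
  planes <- lapply(c(5, 9, 7, 3), function(c) matrix(c, 8, 8))
  expect_equal(thresholdValues(meanStdThreshold(mk(planes))), c(9, 9, 7, 3))
})

test_that("threshold application is strict and depth-wise", {
  arr <- array(0, c(6, 6, 3))
  thr <- new("DepthThreshold", values = c(1, 2, 3), model = list())
  expect_equal(sum(voxelData(applyThreshold(VoxelStack(arr), thr))), 0)
  ## intensity equal to the threshold stays background
  for (k in 1:3) arr[, , k] <- k
  expect_equal(sum(voxelData(applyThreshold(VoxelStack(arr), thr))), 0)
  arr[1, 1, 2] <- 2.5
  expect_equal(sum(voxelData(applyThreshold(VoxelStack(arr), thr))), 1)
})

test_that("edge finder thresholds separate the two intensity levels", {
  ## bright disk on dark background: threshold must fall strictly between
  n <- 48
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  pl <- matrix(20, n, n)
  pl[as.matrix(g[(g$x - 24)^2 + (g$y - 24)^2 <= 100, c("x", "y")])] <- 200
  stack <- VoxelStack(array(rep(pl, 3), c(n, n, 3)))
  thr <- thresholdValues(edgeFinderThreshold(stack))
  expect_true(all(thr > 20 & thr < 200))

  ## a constant plane yields a missing threshold
  stack2 <- VoxelStack(array(20, c(n, n, 1)))
  expect_true(is.na(thresholdValues(edgeFinderThreshold(stack2))[1]))

  ## brute-force oracle: median smoothed intensity over the Otsu edge set
  sm <- pvsmorph:::gaussBlur3d(array(rep(pl, 3), c(n, n, 3)), c(2, 2, 2))
  pls <- sm[, , 2]
  gx <- (pls[c(2:n, n), ] - pls[c(1, 1:(n - 1)), ]) / 2
  gy <- (pls[, c(2:n, n)] - pls[, c(1, 1:(n - 1))]) / 2
  gm <- sqrt(gx^2 + gy^2)
  lev <- pvsmorph:::otsuLevel(gm)
  expect_equal(thr[2], median(pls[gm > lev]))
})

test_that("three-piece refinement fits, fills and stays non-increasing", {
  ## a profile already of three-piece form is reproduced (zero residual)
  z <- 1:40
  truth <- ifelse(z <= 10, 100, ifelse(z >= 30, 40, 100 - 3 * (z - 10)))
  r <- refineThreshold(new("DepthThreshold", values = truth, model = list()))
  expect_equal(thresholdValues(r), truth, tolerance = 1e-9)

  ## noisy three-piece profile: breakpoints recovered within 2 planes
  set.seed(1)
  noisy <- truth + rnorm(40, sd = 2)
  rn <- refineThreshold(new("DepthThreshold", values = noisy, model = list()))
  expect_lte(abs(rn@model$rampStart - 10), 2)
  expect_lte(abs(rn@model$rampEnd - 30), 2)

  ## non-monotone input is forced into a non-increasing profile; missing
  ## entries are filled from the model
  bump <- c(50, 50, 80, 95, 80, NA, 40, 40, NA, 35)
  rb <- refineThreshold(new("DepthThreshold", values = bump, model = list()))
  v <- thresholdValues(rb)
  expect_true(all(diff(v) <= 1e-9))
  expect_false(any(is.na(v)))
  expect_error(refineThreshold(new("DepthThreshold",
                                   values = c(1, NA, NA, 2, NA), model = list())),
               "at least 4")
})

test_that("mask cleanup keeps the right components and is idempotent", {
  sp <- c(1, 1, 1)
  base <- array(FALSE, c(30, 30, 8))
  base[5:25, 10:20, 2:7] <- TRUE           # main solid component
  m1 <- cleanMask(VoxelStack(base, sp), "vessel")
  expect_identical(voxelData(m1), base)

  withSmall <- base
  withSmall[28:29, 28:29, 3] <- TRUE        # 4-px 2D exclave: removed
  m2 <- cleanMask(VoxelStack(withSmall, sp), "vessel", minRegionPx = 5)
  expect_identical(voxelData(m2), base)

  two <- base
  two[27:29, 1:9, 1:8] <- TRUE              # secondary 3D component
  mv <- cleanMask(VoxelStack(two, sp), "vessel")
  expect_identical(voxelData(mv), base)     # vessel keeps only the largest
  mp <- cleanMask(VoxelStack(two, sp), "pvs")
  expect_identical(voxelData(mp), two)      # pvs keeps the two largest

  ## annulus plane region: interior hole filled
  ann <- array(FALSE, c(30, 30, 1))
  g <- expand.grid(x = 1:30, y = 1:30)
  rr <- (g$x - 15)^2 + (g$y - 15)^2
  ann[cbind(as.matrix(g[rr <= 100 & rr >= 36, ]), 1)] <- TRUE
  mf <- cleanMask(VoxelStack(ann, sp), "vessel")
  expect_true(all(voxelData(mf)[cbind(as.matrix(g[rr <= 100, ]), 1)]))

  ## idempotence
  once <- cleanMask(VoxelStack(two, sp), "pvs")
  twice <- cleanMask(once, "pvs")
  expect_identical(voxelData(once), voxelData(twice))
})

test_that("overlap resolution produces disjoint masks", {
  sp <- c(1, 1, 1)
  a <- array(FALSE, c(10, 10, 2)); a[1:5, , ] <- TRUE
  b <- array(FALSE, c(10, 10, 2)); b[6:10, , ] <- TRUE
  r <- resolveOverlap(VoxelStack(a, sp), VoxelStack(b, sp))
  expect_identical(voxelData(r$vessel), a)
  expect_identical(voxelData(r$pvs), b)

  b2 <- b; b2[5, 1:5, 1] <- TRUE            # 5-voxel overlap
  r2 <- resolveOverlap(VoxelStack(a, sp), VoxelStack(b2, sp), "vessel")
  expect_equal(sum(voxelData(r2$pvs)), sum(b2) - 5)
  expect_equal(sum(voxelData(r2$vessel) & voxelData(r2$pvs)), 0)
  r3 <- resolveOverlap(VoxelStack(a, sp), VoxelStack(b2, sp), "pvs")
  expect_equal(sum(voxelData(r3$vessel)), sum(a) - 5)

  set.seed(4)
  for (i in 1:20) {
    p <- randomMaskPair()
    rr <- resolveOverlap(VoxelStack(array(p$a, c(24, 24, 1)), sp),
                         VoxelStack(array(p$b, c(24, 24, 1)), sp))
    expect_equal(sum(voxelData(rr$vessel) & voxelData(rr$pvs)), 0)
    expect_true(all(as.vector(voxelData(rr$vessel) | voxelData(rr$pvs)) <=
                      as.vector(p$a | p$b)))
  }
})

test_that("overlap fraction and Dice obey their identities", {
  m <- matrix(FALSE, 6, 6); m[2:4, 2:4] <- TRUE
  expect_equal(overlapFraction(m, m), 1)
  expect_equal(dice3d(m, m), 1)
  d <- matrix(FALSE, 6, 6); d[6, 6] <- TRUE
  expect_equal(overlapFraction(m, d), 0)
  expect_equal(dice3d(m, d), 0)
  a <- matrix(FALSE, 4, 4); a[1:2, 1] <- TRUE
  b <- matrix(FALSE, 4, 4); b[2:3, 1] <- TRUE
  expect_equal(overlapFraction(a, b), 1 / 3)
  expect_equal(dice3d(a, b), 0.5)
  e <- matrix(FALSE, 4, 4)
  expect_error(overlapFraction(e, e), "empty")
  expect_error(dice3d(e, e), "empty")

  ## Jaccard never exceeds Dice
  set.seed(2)
  for (i in 1:100) {
    p <- randomMaskPair()
    if (!any(p$a | p$b)) next
    expect_lte(overlapFraction(p$a, p$b), dice3d(p$a, p$b))
  }
})

test_that("2D-to-3D registration recovers depth, rotation and shift", {
  stk <- realisticStack()$vessel
  arr <- voxelData(stk)
  sub <- VoxelStack(arr[, , 21:31], voxelSpacing(stk))
  ref <- arr[, , 26]
  r <- register2dTo3d(ref, sub, maxAngle = 5, maxShift = 10)
  expect_equal(r$depth, 6)
  expect_lt(abs(r$angle), 0.5 * pi / 180)
  expect_equal(r$shift, c(0, 0))

  ## rotated and translated reference
  rot <- pvsmorph:::.rotate2d(ref, -3 * pi / 180)
  shifted <- rot
  shifted[] <- 0
  shifted[5:160, 1:118] <- rot[1:156, 3:120]
  r2 <- register2dTo3d(shifted, sub, maxAngle = 6, maxShift = 10)
  expect_equal(r2$depth, 6)
  expect_lt(abs(r2$angle - 3 * pi / 180), 0.5 * pi / 180)
  ## the reported transform aligns the reference onto the stack plane, so
  ## it is the inverse of the applied content shift of (+4, -2)
  expect_lt(max(abs(r2$shift - c(-4, 2))), 0.51)

  ## uncorrelated noise fails the similarity floor
  set.seed(8)
  noise <- matrix(runif(length(ref), 0, 65535), nrow(ref), ncol(ref))
  expect_error(register2dTo3d(noise, sub, maxAngle = 3, maxShift = 6),
               "registration failed")
})

test_that("refined thresholds are non-increasing on rendered stacks", {
  thr <- refineThreshold(edgeFinderThreshold(realisticStack()$vessel))
  expect_true(all(diff(thresholdValues(thr)) <= 1e-9))
})
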