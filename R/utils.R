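## Internal numerical helpers shared across modules.

normalizeVec <- function(v) v / sqrt(sum(v^2))

## Trilinear interpolation of a 3D array at continuous 1-based voxel
## coordinates (n x 3 matrix). Points outside the grid return `fill`.
trilinear <- function(arr, pts, fill = 0) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, nrow(pts))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  i0 <- pmin(floor(x), d[1] - 1L); j0 <- pmin(floor(y), d[2] - 1L)
  k0 <- pmin(floor(z), d[3] - 1L)
  if (d[1] == 1L) i0 <- rep(1, length(x))
  if (d[2] == 1L) j0 <- rep(1, length(y))
  if (d[3] == 1L) k0 <- rep(1, length(z))
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  g <- function(i, j, k) arr[cbind(pmin(i, d[1]), pmin(j, d[2]), pmin(k, d[3]))]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * g(i0, j0, k0) +
       fx * (1 - fy) * (1 - fz) * g(i0 + 1, j0, k0) +
       (1 - fx) * fy * (1 - fz) * g(i0, j0 + 1, k0) +
       fx * fy * (1 - fz) * g(i0 + 1, j0 + 1, k0) +
       (1 - fx) * (1 - fy) * fz * g(i0, j0, k0 + 1) +
       fx * (1 - fy) * fz * g(i0 + 1, j0, k0 + 1) +
       (1 - fx) * fy * fz * g(i0, j0 + 1, k0 + 1) +
       fx * fy * fz * g(i0 + 1, j0 + 1, k0 + 1)
  out[ok] <- v
  out
}

## Truncated, edge-renormalized 1D Gaussian kernel (sigma in samples).
gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

## Convolve a 3D array along one axis with kernel k (banded sparse matrix,
## rows renormalized at the edges so constants are preserved).
convolveAxis <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr)
  d <- dim(arr)
  n <- d[axis]
  r <- (length(k) - 1L) / 2L
  if (r >= n) {  # kernel wider than the axis: truncate to fit
    k <- k[(r - n + 2):(r + n)]
    r <- n - 1L
  }
  off <- seq(-r, r)
  B <- Matrix::bandSparse(n, n, k = off,
                          diagonals = lapply(off, function(o) rep(k[o + r + 1], n - abs(o))))
  B <- B / Matrix::rowSums(B)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = n)
  m <- as.matrix(B %*% m)
  dim(m) <- da
  aperm(m, order(perm))
}

## Separable 3D Gaussian blur; sigma per axis in voxels.
gaussBlur3d <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3)
  for (ax in 1:3)
    if (sigma[ax] > 0) arr <- convolveAxis(arr, gaussKernel(sigma[ax]), ax)
  arr
}

## 3D connected-component labeling: per-plane 2D labels (EBImage::bwlabel)
## stitched across depth wherever labels overlap in consecutive planes.
## Returns an integer array (0 = background).
label3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- integer(d[3])
  nlab <- 0L
  for (k in seq_len(d[3])) {
    lk <- EBImage::bwlabel(mask[, , k])
    offs[k] <- nlab
    mk <- max(lk)
    lk[lk > 0] <- lk[lk > 0] + nlab
    nlab <- nlab + mk
    lab[, , k] <- lk
  }
  if (nlab == 0L) return(lab)
  parent <- seq_len(nlab)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(d[3] - 1L)) {
    a <- lab[, , k]; b <- lab[, , k + 1L]
    both <- a > 0 & b > 0
    if (!any(both)) next
    pairs <- unique(cbind(a[both], b[both]))
    for (r in seq_len(nrow(pairs))) {
      ra <- findRoot(pairs[r, 1]); rb <- findRoot(pairs[r, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(nlab), findRoot, integer(1))
  remap <- match(roots, unique(roots))
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

## Otsu threshold of a numeric vector (wraps EBImage::otsu on a normalized
## single-row image). Returns the threshold on the original scale, or NA
## when the input has no spread.
otsuLevel <- function(x) {
  x <- x[is.finite(x)]
  rg <- range(x)
  if (diff(rg) <= 0) return(NA_real_)
  xn <- (x - rg[1]) / diff(rg)
  t <- EBImage::otsu(EBImage::Image(matrix(xn, nrow = 1)), range = c(0, 1))
  rg[1] + t * diff(rg)
}

## Evaluate f() with a transient RNG seed.
withSeed <- function(seed, f) withr::with_seed(as.integer(seed), f())

## Shoelace signed area of a closed ring given as a list/matrix of x, y.
ringArea <- function(x, y) {
  n <- length(x)
  0.5 * sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
}

## Even-odd point-in-polygon test against a list of rings
## (each ring: list(x=, y=)). Vectorized over points.
pointInRings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (rg in rings) {
    x <- rg$x; y <- rg$y
    n <- length(x)
    j <- c(n, seq_len(n - 1L))
    for (e in seq_len(n)) {
      x1 <- x[j[e]]; y1 <- y[j[e]]; x2 <- x[e]; y2 <- y[e]
      crosses <- ((y1 > py) != (y2 > py))
      if (any(crosses)) {
        xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
        hit <- crosses
        hit[crosses] <- px[crosses] < xint
        inside <- xor(inside, hit)
      }
    }
  }
  inside
}

## Total enclosed area of an even-odd ring set.
ringsArea <- function(rings) {
  if (!length(rings)) return(0)
  areas <- vapply(rings, function(r) abs(ringArea(r$x, r$y)), numeric(1))
  depth <- vapply(seq_along(rings), function(i) {
    sum(vapply(seq_along(rings), function(j) {
      if (i == j) return(FALSE)
      pointInRings(rings[[i]]$x[1], rings[[i]]$y[1], rings[j])
    }, logical(1)))
  }, numeric(1))
  sum(areas * ifelse(depth %% 2 == 0, 1, -1))
}
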