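## Synthetic two-photon stack generator: a gently curved vessel tube with a
## two-lobed perivascular space, rendered with depth attenuation, a shadow
## under the lumen, optical blur and mixed Gaussian/shot noise, plus exact
## ground-truth masks and shape parameters.

#' Ground-truth geometry of a synthetic vessel + PVS segment
#'
#' The vessel axis runs along x as the quadratic curve
#' `(x, y(x), z(x))`; the cross-section in the local normal frame is a
#' vessel circle of radius R1 plus a two-lobed polynomial PVS. Profiles
#' (R1, lobe widths and heights, HC) vary smoothly with arclength as
#' sinusoidal modulations of their base values, so the exact shape at any
#' station is recoverable (`groundTruthSections`).
#'
#' @slot coefY,coefZ quadratic coefficients c(a, b, c) of y(x), z(x) (um).
#' @slot xRange extent of the axis along x (um).
#' @slot profiles named list of profile descriptors
#'   (base, amp, period, phase).
#' @slot roll roll angle of the PVS plane about the tangent (radians).
#' @slot dims volume size in voxels.
#' @slot spacing voxel pitch (um).
#' @export
setClass("GroundTruthGeometry",
  representation(coefY = "numeric", coefZ = "numeric", xRange = "numeric",
                 profiles = "list", roll = "numeric", dims = "integer",
                 spacing = "numeric"))

setMethod("show", "GroundTruthGeometry", function(object) {
  b <- vapply(object@profiles, `[[`, numeric(1), "base")
  cat(sprintf("GroundTruthGeometry: %d x %d x %d voxels, axis %.0f-%.0f um\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@xRange[1], object@xRange[2]))
  cat(sprintf("  base R1 %.1f | H1 %.1f | H2 %.1f | H3 %.2f | HC %.3f | W %.1f/%.1f um\n",
              b["r1"], b["h1"], b["h2"], b["h3"], b["hC"],
              b["wLeft"], b["wRight"]))
})

#' Imaging model for stack rendering
#'
#' Describes the two-photon-like degradations applied to the noiseless
#' rendering. The attenuation length, shadow factor and noise amplitudes
#' are modeling assumptions (documented in the methods vignette), not
#' measured values.
#'
#' @slot attenuationLength depth scale of exponential intensity decay (um).
#' @slot shadowFactor multiplicative attenuation under the vessel lumen
#'   (1 = no shadow).
#' @slot psfSigma Gaussian blur sigma per axis (um).
#' @slot readNoise additive Gaussian noise sigma (intensity counts).
#' @slot shotNoise signal-dependent noise coefficient
#'   (sigma = shotNoise * sqrt(I)).
#' @slot baseVessel,basePvs tracer signal amplitudes (counts).
#' @slot background tissue autofluorescence level (attenuated with depth).
#' @slot offset constant detector dark level (not attenuated).
#' @slot bitDepth output bit depth (values clipped to 0..2^bitDepth - 1).
#' @slot jitterAmp optional per-plane cardiac jitter of the rendered vessel
#'   radius, as a fraction of the diameter (0 = off).
#' @export
setClass("ImagingModel",
  representation(attenuationLength = "numeric", shadowFactor = "numeric",
                 psfSigma = "numeric", readNoise = "numeric",
                 shotNoise = "numeric", baseVessel = "numeric",
                 basePvs = "numeric", background = "numeric",
                 offset = "numeric", bitDepth = "numeric",
                 jitterAmp = "numeric"),
  validity = function(object) {
    if (object@shadowFactor < 0 || object@shadowFactor > 1)
      return("shadowFactor must lie in [0, 1]")
    if (any(object@psfSigma < 0)) return("psfSigma must be >= 0")
    TRUE
  })

#' @rdname ImagingModel-class
#' @param attenuationLength,shadowFactor,psfSigma,readNoise,shotNoise
#'   degradation parameters, see slots.
#' @param baseVessel,basePvs,background,offset intensity levels.
#' @param bitDepth output bit depth.
#' @param jitterAmp cardiac-jitter amplitude (fraction of vessel diameter).
#' @export
imagingModel <- function(attenuationLength = 150, shadowFactor = 0.5,
                         psfSigma = c(0.5, 0.5, 1.5), readNoise = 100,
                         shotNoise = 1.5, baseVessel = 12000, basePvs = 9000,
                         background = 100, offset = 150, bitDepth = 16,
                         jitterAmp = 0) {
  new("ImagingModel", attenuationLength = attenuationLength,
      shadowFactor = shadowFactor, psfSigma = rep(psfSigma, length.out = 3),
      readNoise = readNoise, shotNoise = shotNoise, baseVessel = baseVessel,
      basePvs = basePvs, background = background, offset = offset,
      bitDepth = bitDepth, jitterAmp = jitterAmp)
}

#' @rdname ImagingModel-class
#' @param preset `"clean"` (degenerate model: no attenuation, shadow, blur
#'   or noise) or `"realistic"` (default degradations).
#' @export
imagingPreset <- function(preset = c("realistic", "clean")) {
  preset <- match.arg(preset)
  if (preset == "clean")
    imagingModel(attenuationLength = Inf, shadowFactor = 1,
                 psfSigma = c(0, 0, 0), readNoise = 0, shotNoise = 0,
                 offset = 0)
  else imagingModel()
}

#' Default configuration of the synthetic geometry
#'
#' Base shape parameters sit at the peak values of the in-vivo polynomial
#' fit distributions (R1 20.8, H1 39.5, H2 18.6, H3 9.37, HC 0.799, short
#' width 22.3 and long width 42.1 um); profiles are constant unless
#' `variationAmp > 0`. Volume defaults to the acquisition size of
#' 512 x 512 x 150 voxels at 0.648 x 0.648 x 1 um.
#'
#' @return Named list of configuration values.
#' @export
syntheticConfig <- function() {
  list(dims = c(512L, 512L, 150L), spacing = c(0.648, 0.648, 1),
       r1 = 20.8, h1 = 39.5, h2 = 18.6, h3 = 9.37, hC = 0.799,
       wLeft = 22.3, wRight = 42.1,
       depth = 70, curvatureY = 2e-4, curvatureZ = 1e-4,
       variationAmp = 0, variationPeriod = 200, roll = 0)
}

profileEval <- function(geom, name, s) {
  p <- geom@profiles[[name]]
  p$base * (1 + p$amp * sin(2 * pi * s / p$period + p$phase))
}

## arclength lookup s(x) along the quadratic axis
.arcTable <- function(geom, n = 2001) {
  x <- seq(geom@xRange[1], geom@xRange[2], length.out = n)
  dy <- geom@coefY[2] + 2 * geom@coefY[3] * x
  dz <- geom@coefZ[2] + 2 * geom@coefZ[3] * x
  ds <- sqrt(1 + dy^2 + dz^2)
  s <- c(0, cumsum((ds[-1] + ds[-n]) / 2 * diff(x)))
  list(x = x, s = s)
}

#' Generate a ground-truth vessel + PVS geometry
#'
#' @param config list of configuration values; defaults from
#'   [syntheticConfig()] are used for anything omitted.
#' @param seed integer seed; drives the random modulation phases when
#'   `variationAmp > 0`.
#' @return A [GroundTruthGeometry-class].
#' @export
generateGeometry <- function(config = list(), seed = 1) {
  cfg <- utils::modifyList(syntheticConfig(), config)
  for (nm in c("r1", "h1", "h2", "h3", "wLeft", "wRight"))
    if (cfg[[nm]] <= 0 && nm != "h3")
      stop(sprintf("configuration value '%s' must be positive", nm))
  if (any(c(cfg$h1, cfg$h2, cfg$h3) < 0))
    stop("lobe heights must be non-negative")
  dims <- as.integer(cfg$dims)
  phases <- withSeed(seed, function() runif(7, 0, 2 * pi))
  names(phases) <- c("r1", "h1", "h2", "h3", "hC", "wLeft", "wRight")
  amp <- cfg$variationAmp
  profiles <- lapply(names(phases), function(nm)
    list(base = cfg[[nm]], amp = if (nm == "hC") 0 else amp,
         period = cfg$variationPeriod, phase = unname(phases[nm])))
  names(profiles) <- names(phases)
  y0 <- (dims[2] - 1) * cfg$spacing[2] / 2
  xmax <- (dims[1] - 1) * cfg$spacing[1]
  xc <- xmax / 2
  ## y(x) = y0 + ky (x - xc)^2, expanded in standard form
  coefY <- c(y0 + cfg$curvatureY * xc^2, -2 * cfg$curvatureY * xc, cfg$curvatureY)
  coefZ <- c(cfg$depth + cfg$curvatureZ * xc^2, -2 * cfg$curvatureZ * xc,
             cfg$curvatureZ)
  new("GroundTruthGeometry", coefY = coefY, coefZ = coefZ,
      xRange = c(0, xmax), profiles = profiles, roll = cfg$roll,
      dims = dims, spacing = as.numeric(cfg$spacing))
}

#' Exact cross-section shapes at given arclengths
#'
#' Returns the true [PolynomialShape-class] (vessel-centered normal-plane
#' frame) at each requested arclength; these are the oracles for the
#' parameter-recovery tests.
#'
#' @param geometry a [GroundTruthGeometry-class].
#' @param arclengths stations in um, within `[0, L]`.
#' @return List of [PolynomialShape-class] objects.
#' @export
groundTruthSections <- function(geometry, arclengths) {
  tab <- .arcTable(geometry)
  if (any(arclengths < 0 | arclengths > max(tab$s)))
    stop(sprintf("arclength out of range [0, %.1f]", max(tab$s)))
  lapply(arclengths, function(s)
    polynomialShape(r1 = profileEval(geometry, "r1", s),
                    wLeft = profileEval(geometry, "wLeft", s),
                    wRight = profileEval(geometry, "wRight", s),
                    h1 = NA, h2 = NA, h3 = NA,
                    hC = profileEval(geometry, "hC", s),
                    h1Left = profileEval(geometry, "h1", s),
                    h2Left = profileEval(geometry, "h2", s),
                    h3Left = profileEval(geometry, "h3", s),
                    h1Right = profileEval(geometry, "h1", s),
                    h2Right = profileEval(geometry, "h2", s),
                    h3Right = profileEval(geometry, "h3", s)))
}

## Lagrange evaluation of the lobe bottom quadratic through
## (x1, y1), (x2, y2), (x3, y3) at h, vectorized over voxels.
.lagrange3 <- function(h, x1, x2, x3, y1, y2, y3) {
  y1 * (h - x2) * (h - x3) / ((x1 - x2) * (x1 - x3)) +
  y2 * (h - x1) * (h - x3) / ((x2 - x1) * (x2 - x3)) +
  y3 * (h - x1) * (h - x2) / ((x3 - x1) * (x3 - x2))
}

#' Render a two-channel synthetic stack with ground truth
#'
#' Rasterizes the geometry into exact vessel/PVS masks (the PVS channel is
#' dark inside the lumen, which carries no CSF tracer), then renders
#' intensities: base level times exponential depth attenuation, times the
#' shadow factor for voxels lying below any lumen voxel in the same (x, y)
#' column, followed by separable Gaussian blur and additive Gaussian plus
#' signal-dependent noise. The same seed and parameters give a bit-identical
#' stack.
#'
#' @param geometry a [GroundTruthGeometry-class].
#' @param imaging an [ImagingModel-class].
#' @param seed integer seed for jitter and noise.
#' @return List with `vessel`, `pvs` (intensity [VoxelStack-class]s) and
#'   `vesselMask`, `pvsMask` (logical [VoxelStack-class]s).
#' @export
renderStack <- function(geometry, imaging = imagingPreset("realistic"),
                        seed = 1) {
  d <- geometry@dims; sp <- geometry@spacing
  tab <- .arcTable(geometry)
  prof <- geometry@profiles
  ## bounds check: lateral and depth extents with a 2 um margin
  up <- max(prof$r1$base, prof$r1$base + prof$hC$base) * (1 + abs(prof$r1$amp))
  down <- max(prof$r1$base,
              prof$h1$base * (1 + abs(prof$h1$amp)) - prof$r1$base - prof$hC$base)
  lat <- prof$r1$base + max(prof$wLeft$base, prof$wRight$base)
  lat <- lat * (1 + max(abs(prof$r1$amp), abs(prof$wLeft$amp)))
  yDev <- max(abs(geometry@coefY[1] + geometry@coefY[2] * tab$x +
                  geometry@coefY[3] * tab$x^2 - (d[2] - 1) * sp[2] / 2))
  zs <- geometry@coefZ[1] + geometry@coefZ[2] * tab$x + geometry@coefZ[3] * tab$x^2
  if (lat + yDev + 2 > (d[2] - 1) * sp[2] / 2)
    stop(sprintf("lateral extent %.1f um exceeds the volume half-width %.1f um",
                 lat + yDev, (d[2] - 1) * sp[2] / 2))
  if (max(zs) + down + 2 > (d[3] - 1) * sp[3] || min(zs) - up - 2 < 0)
    stop(sprintf("depth extent [%.1f, %.1f] um exceeds the volume depth range [0, %.1f] um",
                 min(zs) - up, max(zs) + down, (d[3] - 1) * sp[3]))

  vesselMask <- array(FALSE, d); pvsMask <- array(FALSE, d)
  iv <- array(0, d); ip <- array(0, d)
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  X <- matrix(xs, d[1], d[2]); Y <- matrix(ys, d[1], d[2], byrow = TRUE)
  cy <- geometry@coefY; cz <- geometry@coefZ

  withSeed(seed, function() {
    jit <- if (imaging@jitterAmp > 0)
      runif(d[3], -1, 1) * imaging@jitterAmp else numeric(d[3])
    shadowAbove <- matrix(FALSE, d[1], d[2])
    for (k in seq_len(d[3])) {
      z <- (k - 1) * sp[3]
      ## project each voxel of the plane onto the axis (Newton on the
      ## orthogonality condition; the axis is gently curved so x is a good
      ## starting value)
      t <- X
      for (it in 1:4) {
        Yt <- cy[1] + cy[2] * t + cy[3] * t^2
        Zt <- cz[1] + cz[2] * t + cz[3] * t^2
        dY <- cy[2] + 2 * cy[3] * t; dZ <- cz[2] + 2 * cz[3] * t
        f <- (X - t) + (Y - Yt) * dY + (z - Zt) * dZ
        fp <- -1 - dY^2 - dZ^2 + (Y - Yt) * 2 * cy[3] + (z - Zt) * 2 * cz[3]
        t <- t - f / fp
      }
      t <- pmin(pmax(t, geometry@xRange[1]), geometry@xRange[2])
      Yt <- cy[1] + cy[2] * t + cy[3] * t^2
      Zt <- cz[1] + cz[2] * t + cz[3] * t^2
      dY <- cy[2] + 2 * cy[3] * t; dZ <- cz[2] + 2 * cz[3] * t
      nT <- sqrt(1 + dY^2 + dZ^2)
      ## frame: u transverse-horizontal, v = T x u oriented up (-z)
      nU <- sqrt(1 + dY^2)
      ux <- -dY / nU; uy <- 1 / nU
      vx <- uy * dZ / nT; vy <- -ux * dZ / nT
      vz <- (ux * dY - uy) / nT
      flip <- vz > 0
      vx[flip] <- -vx[flip]; vy[flip] <- -vy[flip]; vz[flip] <- -vz[flip]
      if (geometry@roll != 0) {
        cr <- cos(geometry@roll); sr <- sin(geometry@roll)
        ux2 <- ux * cr + vx * sr; uy2 <- uy * cr + vy * sr
        uz2 <- vz * sr
        vx <- -ux * sr + vx * cr; vy <- -uy * sr + vy * cr; vz <- vz * cr
        ux <- ux2; uy <- uy2; uz <- uz2
      } else uz <- 0
      ddx <- X - t; ddy <- Y - Yt; ddz <- z - Zt
      H <- ddx * ux + ddy * uy + ddz * uz
      V <- ddx * vx + ddy * vy + ddz * vz
      s <- approx(tab$x, tab$s, t, rule = 2)$y
      r1 <- profileEval(geometry, "r1", s)
      h1 <- profileEval(geometry, "h1", s)
      h2 <- profileEval(geometry, "h2", s)
      h3 <- profileEval(geometry, "h3", s)
      hC <- profileEval(geometry, "hC", s)
      wL <- profileEval(geometry, "wLeft", s)
      wR <- profileEval(geometry, "wRight", s)
      vtop <- r1 + hC
      r2 <- H^2 + V^2
      vess <- r2 <= r1^2
      aH <- abs(H)
      mid <- aH < r1 & !vess & V > sqrt(pmax(0, r1^2 - H^2)) & V <= vtop
      bR <- .lagrange3(H, r1, r1 + wR / 2, r1 + wR,
                       vtop - h1, vtop - h2, vtop - h3)
      right <- H >= r1 & H <= r1 + wR & V >= bR & V <= vtop & !vess
      bL <- .lagrange3(-H, r1, r1 + wL / 2, r1 + wL,
                       vtop - h1, vtop - h2, vtop - h3)
      left <- H <= -r1 & H >= -(r1 + wL) & V >= bL & V <= vtop & !vess
      pvs <- mid | right | left
      vesselMask[, , k] <<- vess
      pvsMask[, , k] <<- pvs
      ## rendered lumen may pulse with the cardiac phase of this plane
      if (jit[k] != 0) {
        r1j <- r1 * (1 + jit[k])
        vessR <- r2 <= r1j^2
        pvsR <- pvs & !vessR
      } else {
        vessR <- vess; pvsR <- pvs
      }
      att <- if (is.finite(imaging@attenuationLength))
        exp(-z / imaging@attenuationLength) else 1
      fac <- att * ifelse(shadowAbove, imaging@shadowFactor, 1)
      iv[, , k] <<- imaging@offset +
        (imaging@background + imaging@baseVessel * vessR) * fac
      ipk <- imaging@background + imaging@basePvs * pvsR
      ipk[vessR] <- 0   # blood carries no CSF tracer and blocks autofluorescence
      ip[, , k] <<- imaging@offset + ipk * fac
      shadowAbove <- shadowAbove | vessR
    }
    if (any(imaging@psfSigma > 0)) {
      sv <- imaging@psfSigma / sp
      iv <<- gaussBlur3d(iv, sv)
      ip <<- gaussBlur3d(ip, sv)
    }
    if (imaging@readNoise > 0 || imaging@shotNoise > 0) {
      n <- prod(d)
      iv <<- iv + rnorm(n, sd = imaging@readNoise) +
        imaging@shotNoise * sqrt(pmax(iv, 0)) * rnorm(n)
      ip <<- ip + rnorm(n, sd = imaging@readNoise) +
        imaging@shotNoise * sqrt(pmax(ip, 0)) * rnorm(n)
    }
  })
  top <- 2^imaging@bitDepth - 1
  iv <- round(pmin(pmax(iv, 0), top)); dim(iv) <- d
  ip <- round(pmin(pmax(ip, 0), top)); dim(ip) <- d
  list(vessel = VoxelStack(iv, sp), pvs = VoxelStack(ip, sp),
       vesselMask = VoxelStack(vesselMask, sp),
       pvsMask = VoxelStack(pvsMask, sp))
}
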