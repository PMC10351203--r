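# Shared fixtures. The synthetic volume is sized down from the acquisition
# default so the full render-segment-section-fit chain stays fast; shape
# parameters keep the same proportions as the generator defaults.

.fixtures <- new.env(parent = emptyenv())

smallSimConfig <- function() {
  list(dims = c(160L, 120L, 64L), r1 = 8, h1 = 15, h2 = 8, h3 = 4,
       hC = 0.8, wLeft = 10, wRight = 16, depth = 26,
       curvatureY = 3e-4, curvatureZ = 1.5e-4)
}

smallGeometry <- function() {
  if (is.null(.fixtures$geom))
    .fixtures$geom <- generateGeometry(smallSimConfig(), seed = 7)
  .fixtures$geom
}

cleanStack <- function() {
  if (is.null(.fixtures$clean))
    .fixtures$clean <- renderStack(smallGeometry(), imagingPreset("clean"),
                                   seed = 3)
  .fixtures$clean
}

realisticStack <- function() {
  if (is.null(.fixtures$realistic))
    .fixtures$realistic <- renderStack(smallGeometry(),
                                       imagingPreset("realistic"), seed = 3)
  .fixtures$realistic
}

cleanSegmentation <- function() {
  if (is.null(.fixtures$cleanSeg)) {
    stk <- cleanStack()
    v <- segmentChannel(stk$vessel, "vessel")
    p <- segmentChannel(stk$pvs, "pvs")
    .fixtures$cleanSeg <- resolveOverlap(v$mask, p$mask)
  }
  .fixtures$cleanSeg
}

realisticSegmentation <- function() {
  if (is.null(.fixtures$realSeg)) {
    stk <- realisticStack()
    v <- segmentChannel(stk$vessel, "vessel")
    p <- segmentChannel(stk$pvs, "pvs")
    .fixtures$realSeg <- resolveOverlap(v$mask, p$mask)
  }
  .fixtures$realSeg
}

cleanSections <- function() {
  if (is.null(.fixtures$cleanSections)) {
    seg <- cleanSegmentation()
    isoV <- resampleIsotropic(seg$vessel)
    isoP <- resampleIsotropic(seg$pvs, binarize = FALSE)
    cl <- smoothCenterline(extractCenterline(isoV))
    secs <- extractSections(resampleIsotropic(seg$vessel, binarize = FALSE),
                            isoP, cl, halfWidth = 28)
    .fixtures$cleanSections <- excludeEdgeSections(secs)
  }
  .fixtures$cleanSections
}

# draw a polynomial shape with parameters spanning the published quartile
# ranges of the per-section fit distributions (normalized by R1)
randomQuartileShape <- function() {
  r1 <- runif(1, 19.5, 29.6)
  polynomialShape(r1 = r1,
                  wLeft = runif(1, 1.04, 2.93) * r1,
                  wRight = runif(1, 2.16, 5.23) * r1,
                  h1 = runif(1, 1.17, 1.76) * r1,
                  h2 = runif(1, 0.74, 1.37) * r1,
                  h3 = runif(1, 0.27, 0.71) * r1,
                  hC = runif(1, -0.141, 0.209) * r1,
                  topSlope = runif(1, -0.05, 0.05))
}

# render a rasterized section pair through the realistic imaging
# degradations (blur + read/shot noise at the default amplitudes) and
# re-segment it, emulating a high-SNR single-plane acquisition
noisySection <- function(shape, seed) {
  im <- imagingPreset("realistic")
  sec <- rasterizeSection(shape)
  p <- sec@pixelSize
  degrade <- function(mask, base) {
    img <- im@offset + im@background + base * mask
    img <- array(img, c(dim(mask), 1))
    img <- pvsmorph:::gaussBlur3d(img, c(im@psfSigma[1:2] / p, 0))[, , 1]
    img + rnorm(length(img), sd = im@readNoise) +
      im@shotNoise * sqrt(pmax(img, 0)) * rnorm(length(img))
  }
  withr::with_seed(seed, {
    iv <- degrade(sec@vessel, im@baseVessel)
    ip <- degrade(sec@pvs, im@basePvs)
  })
  thr <- function(img, base) img > im@offset + im@background + base / 2
  vm <- thr(iv, im@baseVessel)
  pm <- thr(ip, im@basePvs)
  clean2d <- function(m) {
    lab <- EBImage::bwlabel(m)
    if (max(lab) == 0) return(m)
    sz <- tabulate(lab[lab > 0])
    m[lab > 0 & sz[pmax(lab, 1)] < 5] <- FALSE
    EBImage::fillHull(m) > 0
  }
  vm <- clean2d(vm); pm <- clean2d(pm) & !vm
  new("VesselSection", vessel = vm, pvs = pm, pixelSize = p,
      center = sec@center, arclength = 0, edgeDistance = Inf,
      outOfBounds = FALSE)
}

# random blobby mask pair for overlap-metric properties
randomMaskPair <- function(n = 24) {
  mk <- function() {
    m <- matrix(FALSE, n, n)
    cx <- runif(1, 6, n - 6); cy <- runif(1, 6, n - 6); r <- runif(1, 3, 8)
    g <- expand.grid(seq_len(n), seq_len(n))
    m[as.matrix(g[(g[, 1] - cx)^2 + (g[, 2] - cy)^2 <= r^2, ])] <- TRUE
    m
  }
  list(a = mk(), b = mk())
}
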