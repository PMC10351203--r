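## End-to-end orchestration: simulate -> segment -> sections -> fit ->
## resistance -> stats, with every stage's artifacts written to disk so any
## stage can be re-run in isolation.

#' Default pipeline configuration
#'
#' @param preset imaging preset, `"clean"` or `"realistic"`.
#' @param seed integer seed funneled to every random stage.
#' @param outDir output directory.
#' @return Named list of configuration values.
#' @export
pipelineConfig <- function(preset = "realistic", seed = 1,
                           outDir = tempfile("pvsrun")) {
  list(preset = preset, seed = seed, outDir = outDir,
       sim = list(),
       segmentation = list(method = "edge", minRegionPx = 5,
                           priority = "vessel"),
       sections = list(spacing = 0.8, halfWidth = NA_real_, stride = 1L),
       fits = c("circle", "ellipse", "spline", "polynomial"),
       resistance = list(mu = .MU_CSF, gradient = .GRAD_REF, stride = 4L,
                         models = c("segmentation", "ellipse", "polynomial",
                                    "spline", "annulus")))
}

.validFits <- c("circle", "ellipse", "spline", "polynomial")

#' Run the full analysis pipeline
#'
#' Executes all stages on a synthetic acquisition: stack simulation,
#' depth-threshold segmentation of both channels, centerline extraction and
#' normal-section sampling, idealized-geometry fits, Poiseuille resistance,
#' and distribution statistics. All artifacts (TIFF stacks and masks,
#' section images, CSV tables, a JSON manifest with the configuration and
#' seed) land in `config$outDir`. Deterministic under a fixed seed.
#'
#' @param config list from [pipelineConfig()] (possibly modified).
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  cfg <- utils::modifyList(pipelineConfig(), config)
  if (!all(cfg$fits %in% .validFits))
    stop(sprintf("unknown fit name in config$fits: %s",
                 paste(setdiff(cfg$fits, .validFits), collapse = ", ")))
  if (!cfg$preset %in% c("clean", "realistic"))
    stop("config$preset must be 'clean' or 'realistic'")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  log <- character(0)
  stamp <- function(stage) {
    el <- proc.time()[["elapsed"]] - t0
    log <<- c(log, sprintf("%-12s done at %7.1f s", stage, el))
  }

  ## -- simulate ---------------------------------------------------------
  geom <- generateGeometry(cfg$sim, seed = cfg$seed)
  stk <- renderStack(geom, imagingPreset(cfg$preset), seed = cfg$seed)
  writeStackTIFF(stk$vessel, file.path(cfg$outDir, "vessel.tif"))
  writeStackTIFF(stk$pvs, file.path(cfg$outDir, "pvs.tif"))
  writeStackTIFF(stk$vesselMask, file.path(cfg$outDir, "vessel_truth.tif"))
  writeStackTIFF(stk$pvsMask, file.path(cfg$outDir, "pvs_truth.tif"))
  stamp("simulate")

  ## -- segment ----------------------------------------------------------
  sc <- cfg$segmentation
  segV <- segmentChannel(stk$vessel, "vessel", method = sc$method,
                         minRegionPx = sc$minRegionPx)
  segP <- segmentChannel(stk$pvs, "pvs", method = sc$method,
                         minRegionPx = sc$minRegionPx)
  res <- resolveOverlap(segV$mask, segP$mask, priority = sc$priority)
  diceV <- dice3d(res$vessel, stk$vesselMask)
  diceP <- dice3d(res$pvs, stk$pvsMask)
  writeStackTIFF(res$vessel, file.path(cfg$outDir, "vessel_mask.tif"))
  writeStackTIFF(res$pvs, file.path(cfg$outDir, "pvs_mask.tif"))
  write.csv(data.frame(depth = seq_along(thresholdValues(segV$threshold)),
                       vessel = thresholdValues(segV$threshold),
                       pvs = thresholdValues(segP$threshold)),
            file.path(cfg$outDir, "thresholds.csv"), row.names = FALSE)
  stamp("segment")

  ## -- sections ---------------------------------------------------------
  isoV <- resampleIsotropic(res$vessel)
  ## soft masks for slicing: binarized once, at the oblique sampling
  isoVs <- resampleIsotropic(res$vessel, binarize = FALSE)
  isoP <- resampleIsotropic(res$pvs, binarize = FALSE)
  cl <- smoothCenterline(extractCenterline(isoV),
                         spacing = cfg$sections$spacing)
  hw <- cfg$sections$halfWidth
  if (is.na(hw)) {
    p <- geom@profiles
    hw <- (p$r1$base + max(p$wLeft$base, p$wRight$base)) * 1.15
  }
  sections <- extractSections(isoVs, isoP, cl, halfWidth = hw,
                              stride = cfg$sections$stride)
  sections <- excludeEdgeSections(sections)
  writeSectionsTIFF(sections, file.path(cfg$outDir, "sections.tif"),
                    file.path(cfg$outDir, "sections.csv"))
  stamp("sections")

  ## -- fit --------------------------------------------------------------
  fits <- lapply(sections, function(s)
    tryCatch(fitSection(s), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  sections <- sections[ok]; fits <- fits[ok]
  fitTab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(section = i, arclength = sections[[i]]@arclength,
               r1 = f$circle@r1, vesselArea = f$vesselArea,
               pvsArea = f$pvsArea, segK = f$K,
               ellipseK = if (!is.null(f$ellipse)) areaRatio(f$ellipse) else NA,
               polyK = if (!is.null(f$polynomial)) areaRatio(f$polynomial) else NA,
               splineK = areaRatio(f$spline),
               hC = if (!is.null(f$polynomial)) f$polynomial@hC else NA,
               wLeft = if (!is.null(f$polynomial)) f$polynomial@wLeft else NA,
               wRight = if (!is.null(f$polynomial)) f$polynomial@wRight else NA)
  }))
  write.csv(fitTab, file.path(cfg$outDir, "fits.csv"), row.names = FALSE)
  stamp("fit")

  ## -- resistance -------------------------------------------------------
  rc <- cfg$resistance
  ridx <- seq(1L, length(sections), by = rc$stride)
  resist <- do.call(rbind, lapply(ridx, function(i) {
    s <- sections[[i]]; f <- fits[[i]]
    safeR <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    rseg <- safeR(solvePoiseuille(maskToFlowDomain(s@pvs, s@pixelSize),
                                  mu = rc$mu, gradient = rc$gradient)@resistance)
    rell <- if ("ellipse" %in% cfg$fits && !is.null(f$ellipse))
      safeR(solvePoiseuille(f$ellipse, mu = rc$mu,
                            gradient = rc$gradient)@resistance) else NA_real_
    rpoly <- if ("polynomial" %in% cfg$fits && !is.null(f$polynomial))
      safeR(solvePoiseuille(f$polynomial, mu = rc$mu,
                            gradient = rc$gradient)@resistance) else NA_real_
    rspl <- if ("spline" %in% cfg$fits)
      safeR(solvePoiseuille(f$spline, mu = rc$mu,
                            gradient = rc$gradient)@resistance) else NA_real_
    rann <- safeR(optimalAnnulusResistance(f$K, f$circle@r1, mu = rc$mu))
    data.frame(section = i, arclength = s@arclength, area = f$pvsArea,
               segmentation = rseg, ellipse = rell, polynomial = rpoly,
               spline = rspl, annulus = rann)
  }))
  write.csv(resist, file.path(cfg$outDir, "resistance.csv"), row.names = FALSE)
  stamp("resistance")

  ## -- stats ------------------------------------------------------------
  sumTab <- function(x) {
    s <- summarizeDistribution(x)
    c(peak = s@peak, q25 = s@q25, q50 = s@q50, q75 = s@q75, iqr = s@iqr)
  }
  Ks <- list(segmentation = fitTab$segK, ellipse = fitTab$ellipseK,
             polynomial = fitTab$polyK, spline = fitTab$splineK)
  kTab <- as.data.frame(t(vapply(Ks, sumTab, numeric(5))))
  kTab <- cbind(model = rownames(kTab), kTab)
  write.csv(kTab, file.path(cfg$outDir, "area_ratio_stats.csv"),
            row.names = FALSE)
  kShare <- bestFitShare(fitTab$segK,
                         Ks[intersect(c("ellipse", "polynomial", "spline"),
                                      names(Ks))])
  okR <- is.finite(resist$segmentation)
  rShare <- bestFitShare(resist$segmentation[okR],
                         lapply(resist[okR, intersect(c("ellipse", "polynomial",
                                                        "spline", "annulus"),
                                                      names(resist))], identity))
  lin <- linearAreaFit(fitTab$vesselArea, fitTab$pvsArea)
  pw <- if (sum(okR) >= 3)
    powerLawFit(resist$area[okR], resist$segmentation[okR]) else NULL
  polyFits <- Filter(Negate(is.null), lapply(fits, `[[`, "polynomial"))
  quint <- tryCatch(quintessentialShape(polyFits), error = function(e) NULL)
  segR <- if (sum(okR) >= 1)
    segmentResistance(resist$segmentation[okR],
                      spacing = cfg$sections$spacing * rc$stride) else NULL
  stamp("stats")

  manifest <- list(package = as.character(utils::packageVersion("pvsmorph")),
                   seed = cfg$seed, preset = cfg$preset,
                   config = cfg[setdiff(names(cfg), "outDir")],
                   dice = list(vessel = diceV, pvs = diceP),
                   nSections = length(sections), log = log)
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log, file.path(cfg$outDir, "pipeline.log"))
  invisible(list(geometry = geom, stacks = stk,
                 masks = res, dice = list(vessel = diceV, pvs = diceP),
                 centerline = cl, sections = sections, fits = fits,
                 fitTable = fitTab, resistance = resist,
                 areaRatioStats = kTab, kShare = kShare, rShare = rShare,
                 linearFit = lin, powerLaw = pw, quintessential = quint,
                 segmentTotal = segR, outDir = cfg$outDir))
}
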