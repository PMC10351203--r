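## TIFF and CSV input/output for pipeline artifacts.

#' Read a multi-page TIFF into a VoxelStack
#'
#' @param path TIFF file, one page per depth plane.
#' @param spacing voxel pitch (um).
#' @param mask logical: binarize at 0.5 of the full scale.
#' @return A [VoxelStack-class].
#' @export
readStackTIFF <- function(path, spacing = c(0.648, 0.648, 1), mask = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[, , k] <- pg
  }
  if (mask) arr <- arr >= 0.5 else arr <- arr * 65535
  VoxelStack(arr, spacing)
}

#' Write a VoxelStack as a multi-page TIFF
#'
#' Intensities are stored as 16-bit; masks as 8-bit 0/1.
#'
#' @param stack a [VoxelStack-class].
#' @param path output file.
#' @export
writeStackTIFF <- function(stack, path) {
  arr <- voxelData(stack)
  d <- dim(arr)
  if (is.logical(arr)) {
    pages <- lapply(seq_len(d[3]), function(k) arr[, , k] * 1.0)
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
  } else {
    pages <- lapply(seq_len(d[3]), function(k)
      pmin(pmax(arr[, , k] / 65535, 0), 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  }
  invisible(path)
}

#' Write sections as a multi-page TIFF plus CSV index
#'
#' Each page encodes one section: vessel pixels 1.0, PVS pixels 0.5,
#' background 0. The CSV index records arclength, the vessel center pixel,
#' pixel size, edge distance and the out-of-bounds flag.
#'
#' @param sections list of [VesselSection-class].
#' @param tiffPath,csvPath output files.
#' @export
writeSectionsTIFF <- function(sections, tiffPath, csvPath) {
  pages <- lapply(sections, function(s) s@vessel * 1.0 + s@pvs * 0.5)
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 8)
  idx <- data.frame(
    section = seq_along(sections),
    arclength = vapply(sections, slot, numeric(1), "arclength"),
    centerH = vapply(sections, function(s) s@center[1], numeric(1)),
    centerV = vapply(sections, function(s) s@center[2], numeric(1)),
    pixelSize = vapply(sections, slot, numeric(1), "pixelSize"),
    edgeDistance = vapply(sections, slot, numeric(1), "edgeDistance"),
    outOfBounds = vapply(sections, slot, logical(1), "outOfBounds"))
  write.csv(idx, csvPath, row.names = FALSE)
  invisible(tiffPath)
}

#' Read sections written by [writeSectionsTIFF()]
#'
#' @param tiffPath,csvPath files produced by [writeSectionsTIFF()].
#' @return List of [VesselSection-class].
#' @export
readSectionsTIFF <- function(tiffPath, csvPath) {
  pages <- tiff::readTIFF(tiffPath, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  idx <- read.csv(csvPath)
  lapply(seq_along(pages), function(i) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    new("VesselSection", vessel = pg > 0.75,
        pvs = pg > 0.25 & pg <= 0.75,
        pixelSize = idx$pixelSize[i],
        center = c(idx$centerH[i], idx$centerV[i]),
        arclength = idx$arclength[i],
        edgeDistance = idx$edgeDistance[i],
        outOfBounds = idx$outOfBounds[i])
  })
}
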