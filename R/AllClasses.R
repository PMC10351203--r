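#' @import methods
#' @importFrom stats coef lm median optimise quantile rnorm runif sd setNames
#'   splinefun approx integrate qt predict fft mvfft var contourLines
#' @importFrom utils head tail write.csv read.csv
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' 3D image volume with per-axis voxel spacing
#'
#' Container for a single-channel 3D fluorescence volume or a binary mask.
#' The third array index is cortical depth (increasing = deeper). Spacing is
#' in micrometers per voxel along (x, y, z).
#'
#' @slot data 3D numeric or logical array.
#' @slot spacing numeric length-3, voxel pitch in um.
#' @export
setClass("VoxelStack",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values (um)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a VoxelStack
#'
#' @param data 3D array (numeric intensities or logical mask).
#' @param spacing voxel pitch in um along (x, y, z);
#'   default the two-photon acquisition pitch 0.648 x 0.648 x 1 um.
#' @return A [VoxelStack-class] object.
#' @export
VoxelStack <- function(data, spacing = c(0.648, 0.648, 1)) {
  new("VoxelStack", data = data, spacing = as.numeric(spacing))
}

#' @describeIn VoxelStack-class raw array accessor
#' @param object,x a VoxelStack
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @export
setMethod("voxelData", "VoxelStack", function(x) x@data)

#' @describeIn VoxelStack-class voxel spacing in um
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @export
setMethod("voxelSpacing", "VoxelStack", function(x) x@spacing)

setMethod("dim", "VoxelStack", function(x) dim(x@data))

setMethod("show", "VoxelStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelStack: %d x %d x %d voxels (%s), spacing %.3f x %.3f x %.3f um\n",
              d[1], d[2], d[3],
              if (is.logical(object@data)) "mask" else "intensity",
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

#' Smoothed vessel centerline with orthonormal section frames
#'
#' Ordered points along the vessel axis, resampled to uniform arclength
#' spacing, with a unit tangent and two unit normals spanning the
#' cross-section plane at every station. `normalU` is the in-plane
#' (transverse) horizontal direction; `normalV` points "up", toward
#' decreasing cortical depth, so section images share the orientation used
#' by the shape fits.
#'
#' @slot points n x 3 matrix of positions (um).
#' @slot tangents,normalU,normalV n x 3 matrices of unit vectors.
#' @slot arclength cumulative arclength at each station (um).
#' @export
setClass("Centerline",
  representation(points = "matrix", tangents = "matrix",
                 normalU = "matrix", normalV = "matrix",
                 arclength = "numeric"),
  validity = function(object) {
    n <- nrow(object@points)
    if (!all(vapply(list(object@tangents, object@normalU, object@normalV),
                    function(m) nrow(m) == n && ncol(m) == 3L, logical(1))))
      return("frame matrices must be n x 3")
    if (length(object@arclength) != n)
      return("arclength length mismatch")
    dots <- c(rowSums(object@tangents * object@normalU),
              rowSums(object@tangents * object@normalV),
              rowSums(object@normalU * object@normalV))
    nrms <- c(rowSums(object@tangents^2), rowSums(object@normalU^2),
              rowSums(object@normalV^2))
    if (max(abs(dots)) > 1e-9 || max(abs(nrms - 1)) > 1e-9)
      return("frames must be orthonormal (tol 1e-9)")
    TRUE
  })

setMethod("show", "Centerline", function(object) {
  n <- nrow(object@points)
  cat(sprintf("Centerline: %d stations, arclength %.1f um, mean spacing %.3f um\n",
              n, max(object@arclength),
              if (n > 1) mean(diff(object@arclength)) else NA_real_))
})

#' @describeIn Centerline-class number of stations
#' @param x a Centerline
#' @export
setMethod("length", "Centerline", function(x) nrow(x@points))

#' Vessel/PVS masks on a centerline-normal plane
#'
#' A square cross-section image pair sampled on the plane normal to the
#' vessel centerline. Matrices are indexed `[h, v]` with h the horizontal
#' (normalU) axis and v the vertical (normalV, up) axis; the vessel center
#' sits at the central pixel after recentering. Pixels are isotropic.
#'
#' @slot vessel,pvs logical matrices (same shape).
#' @slot pixelSize pixel pitch (um).
#' @slot center vessel center in pixel coordinates (h, v).
#' @slot arclength station arclength (um).
#' @slot edgeDistance distance from the vessel center to the nearest lateral
#'   face of the acquisition volume (um); used by the edge-exclusion rule.
#' @slot outOfBounds TRUE when the sampling plane left the volume.
#' @export
setClass("VesselSection",
  representation(vessel = "matrix", pvs = "matrix", pixelSize = "numeric",
                 center = "numeric", arclength = "numeric",
                 edgeDistance = "numeric", outOfBounds = "logical"),
  validity = function(object) {
    if (!identical(dim(object@vessel), dim(object@pvs)))
      return("vessel and pvs masks must have identical shape")
    if (any(object@vessel & object@pvs))
      return("vessel and pvs masks must be disjoint")
    TRUE
  })

setMethod("show", "VesselSection", function(object) {
  d <- dim(object@vessel)
  cat(sprintf(
    "VesselSection @ s = %.1f um: %d x %d px (%.3f um/px), vessel %d px, pvs %d px%s\n",
    object@arclength, d[1], d[2], object@pixelSize,
    sum(object@vessel), sum(object@pvs),
    if (object@outOfBounds) " [out-of-bounds]" else ""))
})

## ---- shape fits ------------------------------------------------------------

#' Circle fit of the vessel lumen
#' @slot center circle center in the section frame (um).
#' @slot r1 vessel radius R1 (um).
#' @export
setClass("CircleFit",
  representation(center = "numeric", r1 = "numeric"),
  validity = function(object) {
    if (length(object@r1) != 1 || !is.finite(object@r1) || object@r1 <= 0)
      return("r1 must be a positive scalar")
    TRUE
  })

setMethod("show", "CircleFit", function(object)
  cat(sprintf("CircleFit: R1 = %.2f um at (%.2f, %.2f)\n",
              object@r1, object@center[1], object@center[2])))

#' Elliptical-annulus fit of the PVS
#'
#' Ellipse sharing the PVS mask's centroid and second central moments, with
#' the fitted vessel circle subtracted. Offsets `oH`, `oV` locate the vessel
#' center relative to the ellipse center.
#'
#' @slot center ellipse center (um, section frame).
#' @slot r2,r3 semi-major/semi-minor axes (um), `r2 >= r3 > 0`.
#' @slot angle major-axis orientation (radians).
#' @slot oH,oV vessel-center offset from the ellipse center (um).
#' @slot r1 vessel radius (um).
#' @export
setClass("EllipseAnnulusFit",
  representation(center = "numeric", r2 = "numeric", r3 = "numeric",
                 angle = "numeric", oH = "numeric", oV = "numeric",
                 r1 = "numeric"),
  validity = function(object) {
    if (!(object@r2 >= object@r3 && object@r3 > 0))
      return("need r2 >= r3 > 0")
    TRUE
  })

setMethod("show", "EllipseAnnulusFit", function(object)
  cat(sprintf(
    "EllipseAnnulusFit: R2 = %.2f, R3 = %.2f um, angle %.1f deg, Oh = %.2f, Ov = %.2f, R1 = %.2f\n",
    object@r2, object@r3, object@angle * 180 / pi,
    object@oH, object@oV, object@r1)))

#' Canonical spline PVS geometry
#'
#' Two-lobed PVS outline built from six spline control points expressed in
#' units of the vessel radius, mirrored across the horizontal and vertical
#' axes, with the vessel circle placed `Of = 0.0667 R1` below the PVS
#' vertical midpoint. The shape depends on R1 only, so its PVS-to-vessel
#' area ratio is a constant of the construction.
#'
#' @slot r1 vessel radius (um).
#' @slot controlPoints 6 x 2 matrix, (horizontal, vertical-top) in um.
#' @slot oF vessel drop below the PVS midline (um).
#' @slot minEndWidth full height of the tapered end, R1/4.5 (um).
#' @export
setClass("SplineShape",
  representation(r1 = "numeric", controlPoints = "matrix", oF = "numeric",
                 minEndWidth = "numeric"),
  validity = function(object) {
    if (object@r1 <= 0) return("r1 must be positive")
    if (!identical(dim(object@controlPoints), c(6L, 2L)))
      return("controlPoints must be 6 x 2")
    TRUE
  })

setMethod("show", "SplineShape", function(object)
  cat(sprintf("SplineShape: R1 = %.2f um, half-width %.2f um, Of = %.3f um\n",
              object@r1, max(object@controlPoints[, 1]), object@oF)))

#' Two-lobed polynomial PVS geometry
#'
#' The PVS upper boundary is a single line spanning both lobes; each lobe's
#' lower boundary is a quadratic. All coefficients are in a vessel-centered
#' frame (origin at the vessel center, v up). Derived measures follow the
#' conventions of the morphometric summaries: per side, W is the horizontal
#' distance from the vessel edge to the end of the lobe, H1/H2/H3 the
#' top-minus-bottom heights at the vessel edge, midway, and the far end, and
#' HC the height of the top line above the vessel top at the vessel-center
#' column (negative when the two lobes are disconnected).
#'
#' @slot r1 vessel radius (um).
#' @slot center vessel center in the section frame (um); (0,0) for
#'   synthetic ground-truth shapes.
#' @slot topLine c(intercept, slope) of the upper boundary v = a + b h.
#' @slot bottomLeft,bottomRight quadratic coefficients c(a, b, c) of
#'   v = a + b h + c h^2 for the left/right lobe lower boundary; NULL when
#'   the side is absent.
#' @slot wLeft,wRight lobe widths (um); NA when absent.
#' @slot h1Left,h2Left,h3Left,h1Right,h2Right,h3Right lobe heights (um).
#' @slot hC signed top-line height above the vessel top (um).
#' @export
setClass("PolynomialShape",
  representation(r1 = "numeric", center = "numeric", topLine = "numeric",
                 bottomLeft = "numericOrNULL", bottomRight = "numericOrNULL",
                 wLeft = "numeric", wRight = "numeric",
                 h1Left = "numeric", h2Left = "numeric", h3Left = "numeric",
                 h1Right = "numeric", h2Right = "numeric", h3Right = "numeric",
                 hC = "numeric"),
  validity = function(object) {
    if (object@r1 <= 0) return("r1 must be positive")
    if (is.null(object@bottomLeft) && is.null(object@bottomRight))
      return("at least one lobe must be present")
    for (w in c(object@wLeft, object@wRight))
      if (!is.na(w) && w <= 0) return("lobe widths must be positive")
    hs <- c(object@h1Left, object@h2Left, object@h3Left,
            object@h1Right, object@h2Right, object@h3Right)
    if (any(!is.na(hs) & hs < -1e-9)) return("lobe heights must be >= 0")
    TRUE
  })

setMethod("show", "PolynomialShape", function(object) {
  cat(sprintf("PolynomialShape: R1 = %.2f um, HC = %.3f um%s\n",
              object@r1, object@hC,
              if (object@hC <= 0) " (lobes disconnected)" else ""))
  cat(sprintf("  left : W = %6.2f  H1 = %6.2f  H2 = %6.2f  H3 = %6.2f um\n",
              object@wLeft, object@h1Left, object@h2Left, object@h3Left))
  cat(sprintf("  right: W = %6.2f  H1 = %6.2f  H2 = %6.2f  H3 = %6.2f um\n",
              object@wRight, object@h1Right, object@h2Right, object@h3Right))
})

#' Poiseuille flow solution on a cross section
#'
#' @slot resistance hydraulic resistance per unit length (Pa s/m^4).
#' @slot flowRate volume flow rate at the reference gradient (m^3/s).
#' @slot gradient pressure gradient (Pa/m).
#' @slot viscosity dynamic viscosity (Pa s).
#' @slot velocity list with grid coordinates (um) and the axial velocity
#'   field (m/s) on interior nodes.
#' @slot meshStats list: grid step (um), interior node count, calibration
#'   error of the equal-area circle (relative).
#' @export
setClass("FlowSolution",
  representation(resistance = "numeric", flowRate = "numeric",
                 gradient = "numeric", viscosity = "numeric",
                 velocity = "list", meshStats = "list"),
  validity = function(object) {
    if (object@resistance <= 0) return("resistance must be positive")
    TRUE
  })

setMethod("show", "FlowSolution", function(object)
  cat(sprintf(
    "FlowSolution: R = %.4g Pa s/m^4 (Q = %.3g m^3/s at %g Pa/m; h = %.3g um, %d nodes)\n",
    object@resistance, object@flowRate, object@gradient,
    object@meshStats$h, object@meshStats$nodes)))

#' Distribution summary used in the morphometric tables
#'
#' Quartiles by linear interpolation between order statistics, Tukey fences
#' at 1.5 IQR, and the histogram peak: the center of the most probable of 20
#' equal-width bins spanning the non-outlier range.
#'
#' @slot peak,q25,q50,q75,iqr,outlierLow,outlierHigh summary values.
#' @slot n number of observations.
#' @export
setClass("DistributionSummary",
  representation(peak = "numeric", q25 = "numeric", q50 = "numeric",
                 q75 = "numeric", iqr = "numeric", outlierLow = "numeric",
                 outlierHigh = "numeric", n = "integer"))

setMethod("show", "DistributionSummary", function(object)
  cat(sprintf(
    "DistributionSummary (n = %d): peak %.4g | q25 %.4g | median %.4g | q75 %.4g | IQR %.4g\n",
    object@n, object@peak, object@q25, object@q50, object@q75, object@iqr)))
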