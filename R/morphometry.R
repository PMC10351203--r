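## Distribution statistics, regressions and model comparison for the
## per-section morphometric measures.

#' Tukey outlier fences
#'
#' `low = q25 - 1.5 IQR`, `high = q75 + 1.5 IQR`, with quartiles by linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param values numeric vector, n >= 4.
#' @return Named numeric c(low, high).
#' @export
outlierBounds <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("need at least 4 values for outlier fences")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(low = q[1] - 1.5 * iqr, high = q[2] + 1.5 * iqr)
}

#' Peak of a distribution via 20 equal bins
#'
#' Histograms the values into 20 equal-width bins and returns the center of
#' the bin with the largest probability density; ties break toward the
#' lower bin. By default the bin range spans the data after excluding Tukey
#' outliers (the convention used for the summary tables); a degenerate
#' range returns the common value.
#'
#' @param values numeric vector.
#' @param bins number of bins (default 20).
#' @param excludeOutliers drop values beyond the Tukey fences first.
#' @return The peak value (bin center).
#' @export
distributionPeak <- function(values, bins = 20, excludeOutliers = TRUE) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  if (excludeOutliers && length(values) >= 4) {
    b <- outlierBounds(values)
    values <- values[values >= b["low"] & values <= b["high"]]
  }
  rg <- range(values)
  if (diff(rg) == 0) return(rg[1])
  edges <- seq(rg[1], rg[2], length.out = bins + 1)
  counts <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                          bins), nbins = bins)
  (edges[which.max(counts)] + edges[which.max(counts) + 1]) / 2
}

#' Summarize a distribution the way the morphometric tables do
#'
#' @param values numeric vector.
#' @return A [DistributionSummary-class].
#' @export
summarizeDistribution <- function(values) {
  values <- values[is.finite(values)]
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  b <- if (length(values) >= 4) outlierBounds(values)
       else c(low = -Inf, high = Inf)
  new("DistributionSummary", peak = distributionPeak(values),
      q25 = q[1], q50 = q[2], q75 = q[3], iqr = q[3] - q[1],
      outlierLow = unname(b["low"]), outlierHigh = unname(b["high"]),
      n = length(values))
}

#' Power-law fit of resistance against area
#'
#' Ordinary least squares on `log R ~ log A`; the exponent's 95% confidence
#' interval comes from the normal-theory standard error of the slope.
#'
#' @param areas positive areas (um^2).
#' @param resistances positive resistances (Pa s/m^4).
#' @return List: `exponent`, `prefactor`, `rSquared`, `ci95` (length 2).
#' @export
powerLawFit <- function(areas, resistances) {
  stopifnot(length(areas) == length(resistances), length(areas) >= 3)
  if (any(areas <= 0) || any(resistances <= 0))
    stop("power-law fit needs positive areas and resistances")
  fit <- lm(log(resistances) ~ log(areas))
  ## a perfect fit has zero residual variance; confint then warns
  ci <- suppressWarnings(stats::confint(fit)[2, ])
  list(exponent = unname(coef(fit)[2]),
       prefactor = exp(unname(coef(fit)[1])),
       rSquared = suppressWarnings(summary(fit)$r.squared),
       ci95 = unname(ci))
}

#' Linear fit of PVS area against vessel area
#'
#' @param vesselAreas,pvsAreas per-section areas (um^2).
#' @return List: `slope`, `intercept`, `rSquared`, `ci95` on the slope.
#' @export
linearAreaFit <- function(vesselAreas, pvsAreas) {
  stopifnot(length(vesselAreas) == length(pvsAreas), length(vesselAreas) >= 3)
  if (var(vesselAreas) == 0) stop("degenerate vessel-area variance")
  fit <- lm(pvsAreas ~ vesselAreas)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       rSquared = suppressWarnings(summary(fit)$r.squared),
       ci95 = unname(suppressWarnings(stats::confint(fit)[2, ])))
}

#' Share of sections best matched by each model
#'
#' For every section, the model whose metric is closest (smallest absolute
#' difference) to the segmentation metric wins; exact ties split their
#' section equally among the tied models. Shares sum to 1.
#'
#' @param segMetric per-section segmentation values.
#' @param fitMetrics named list of per-section model values.
#' @return Named numeric vector of shares.
#' @export
bestFitShare <- function(segMetric, fitMetrics) {
  stopifnot(length(fitMetrics) >= 1)
  mat <- vapply(fitMetrics, function(v) abs(v - segMetric),
                numeric(length(segMetric)))
  if (length(segMetric) == 1) mat <- matrix(mat, nrow = 1)
  shares <- setNames(numeric(length(fitMetrics)), names(fitMetrics))
  for (i in seq_len(nrow(mat))) {
    d <- mat[i, ]
    ok <- is.finite(d)
    if (!any(ok)) next
    best <- which(ok & d == min(d[ok]))
    shares[best] <- shares[best] + 1 / length(best)
  }
  shares / sum(shares)
}

#' Quintessential PVS shape from polynomial-fit distributions
#'
#' Builds the representative cross section whose parameters are the
#' distribution peaks of the per-section polynomial-fit parameters:
#' H1, H2, H3, HC, the short and long widths, and the vessel radius. The
#' short side is placed on the left.
#'
#' @param fits list of [PolynomialShape-class] (n >= 20).
#' @return A [PolynomialShape-class].
#' @export
quintessentialShape <- function(fits) {
  fits <- Filter(function(f) !is.na(f@wLeft) && !is.na(f@wRight), fits)
  if (length(fits) < 20)
    stop("need at least 20 polynomial fits with both lobes present")
  g <- function(f) {
    s <- if (f@wLeft <= f@wRight) "Left" else "Right"
    l <- if (s == "Left") "Right" else "Left"
    c(h1S = slot(f, paste0("h1", s)), h1L = slot(f, paste0("h1", l)),
      h2S = slot(f, paste0("h2", s)), h2L = slot(f, paste0("h2", l)),
      h3S = slot(f, paste0("h3", s)), h3L = slot(f, paste0("h3", l)),
      hC = f@hC, wS = min(f@wLeft, f@wRight), wL = max(f@wLeft, f@wRight),
      r1 = f@r1)
  }
  par <- vapply(fits, g, numeric(10))
  pk <- setNames(as.numeric(apply(par, 1, distributionPeak)), rownames(par))
  polynomialShape(r1 = pk[["r1"]], wLeft = pk[["wS"]], wRight = pk[["wL"]],
                  h1 = NA, h2 = NA, h3 = NA, hC = pk[["hC"]],
                  h1Left = pk[["h1S"]], h2Left = pk[["h2S"]],
                  h3Left = pk[["h3S"]], h1Right = pk[["h1L"]],
                  h2Right = pk[["h2L"]], h3Right = pk[["h3L"]])
}
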