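---
title: "Models and methods behind pvsmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pvsmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsmorph)
```

`pvsmorph` quantifies the size, shape, and hydraulic resistance of pial
perivascular spaces (PVSs) from two-channel 3D fluorescence stacks. This
vignette explains the models each stage implements, the parameters that
matter, the numerical choices, and what the synthetic test bed does and
does not establish about real data.

## The measurement problem

A pial artery runs roughly parallel to the brain surface; its PVS forms
two CSF-filled lobes on either side of the vessel, sometimes joined by a
narrow channel above it. Two-photon stacks image a vascular tracer
(vessel lumen) and a CSF tracer (PVS) at 0.648 × 0.648 × 1 µm voxels,
with signal that decays with cortical depth and is additionally shadowed
beneath the blood column. The analysis must (i) segment both
compartments despite the depth-dependent signal, (ii) measure the PVS in
planes orthogonal to the vessel axis, not in acquisition planes, and
(iii) convert each cross section into a hydraulic resistance, the
quantity that couples anatomy to CSF transport.

## Segmentation

Both channels are segmented by a depth-varying intensity threshold: a
voxel is foreground when its intensity strictly exceeds the threshold of
its depth plane (ties are background; one convention had to be fixed and
the strict inequality makes an all-threshold plane empty rather than
full).

Two threshold estimators are provided.

* **Edge Finder** (default). The stack is smoothed with an isotropic 3D
  Gaussian of σ = 2 voxels. In each plane, gradient magnitude is
  computed by central differences and edge pixels are those above the
  per-plane Otsu level of gradient magnitude; the plane threshold is the
  median smoothed intensity over the edge pixels. Planes whose maximum
  gradient is below 5% of the stack-wide maximum (or numerically zero)
  carry no usable boundary evidence — out-of-tissue planes, or planes
  whose only "structure" is the soft rim of the vessel shadow — and are
  marked missing rather than allowed to drag the refinement toward the
  background level.
* **Mean + SD**. The plane mean plus the plane (population) standard
  deviation, with all planes shallower than the maximum clamped to the
  maximum. A per-plane Otsu profile is included as a comparator only; it
  over-segments low-signal planes.

Raw Edge Finder profiles are not monotone, so they are **refined** to a
three-piece model — constant at shallow depths, linear decrease, constant
at deep depths — by exhaustive least squares over all breakpoint pairs,
with the breakpoints confined to the span of usable planes so both
constant levels are anchored by data, and `high ≥ low` enforced. Missing
planes are filled from the model; the result is non-increasing with
depth by construction. This replaces the interactive fine-tuning a human
operator would do with a deterministic rule.

Cleanup follows three steps with fixed conventions: per-plane removal of
2D components smaller than `minRegionPx` (default 5 px, configurable
5–10), retention of the single largest 3D component for the vessel and
the two largest for the PVS (its two lobes), and per-plane hole filling.
Per-plane (rather than 3D) hole filling was chosen because a two-lobed
PVS can legitimately enclose 3D background; in acquisition planes the
vessel gap between the lobes always reaches the volume border and is
never filled by mistake. Vessel/PVS overlaps are resolved by removing
contested voxels from the non-priority mask (default priority: vessel).

Validation uses intersection-over-union against a registered high-SNR 2D
reference (acceptance conventionally at ≥ 0.70) and the 3D Dice
coefficient. Registration searches depth × a 1° rotation grid, refines
the angle continuously, and recovers translation by FFT
cross-correlation of zero-mean images; it fails below a similarity floor
(default 0.3).

## Centerline and normal sections

Masks are resampled to the finest voxel pitch (0.648 µm) by linear
interpolation. The vessel centerline is estimated as the centroid of the
largest in-plane component in each plane transverse to the dominant
lateral axis. This is a deliberate simplification relative to full 3D
skeletonization: for a single, gently curved, non-branching tube the
plane centroids track the axis to a fraction of a voxel, and the
package's scope excludes bifurcations, where skeletonization would earn
its complexity. Small side stubs shift individual centroids in
proportion to their area and are then absorbed by the smoothing step.

Smoothing fits second-order polynomials to the centerline in the
transverse (XY) and axial planes (the parameterizing axis is the one
with the larger lateral extent), and resamples the fitted curve at
0.8 µm arclength spacing. Each station carries an orthonormal frame: the
tangent from the fit derivatives, `normalU` the in-plane perpendicular
of the transverse fit, and `normalV` perpendicular to both, oriented
toward decreasing cortical depth so "up" in section images means toward
the brain surface; all fit parameters (H₁ above vs below, H_C sign)
inherit this orientation.

Sections are sampled on the `(normalU, normalV)` plane at the isotropic
pitch and recentered on the vessel centroid (two passes; the centroid
lands within one pixel of the image center). Masks are interpolated
trilinearly and binarized at 0.5 — but only once: the isotropic
resampling feeding the slicer keeps the soft 0..1 interpolant
(`resampleIsotropic(..., binarize = FALSE)`), because binarizing twice
erodes structures on the order of one voxel (the thin connecting channel
above the vessel, the tapered lobe tips). With a single binarization the
sampled PVS area agrees with the analytic cross-section area to within
~1.5% at production scale.

Sections are excluded when the sampling plane leaves the volume
laterally or when the vessel center is closer to the nearest lateral
face than the median PVS width divided by 2.5 (strict inequality; a
section exactly at the cutoff is retained). Extending above the surface
or below the deepest plane is not an exclusion: those samples hit empty
space, exactly as in an acquisition.

## Idealized cross-section geometries

All fits work in the section frame (µm, origin at the image center, v
up) and report a half-pixel rasterization correction where a boundary is
read off pixel centers: the topmost inside pixel center sits on average
half a pixel below the true boundary, and symmetric corrections are
applied to top/bottom boundary points, lobe ends, and the circle radius.

* **Vessel circle.** Boundary pixels of the vessel mask; points deeper
  than 3 px (configurable) inside the convex hull of the boundary are
  discarded — an under-segmented, shadowed bottom retracts inward and
  its points fall deep inside the hull — then a Kåsa algebraic fit is
  refined by geometric Gauss–Newton iteration (tolerance 1e-8 µm). Fewer
  than 8 boundary pixels or fewer than 3 surviving points is an error.
* **Elliptical annulus.** The ellipse shares the PVS mask's centroid and
  second central moments (semi-axes twice the square roots of the
  eigenvalues, plus the p²/12 moment of a square pixel); offsets `oH`,
  `oV` place the vessel center relative to the ellipse center.
* **Spline shape.** Six control points at horizontal stations 0–5 R₁
  with top heights (1.1111, 0.85, 0.2667, 0.1111, 0.1111, 0.1111) R₁,
  joined by a clamped cubic spline (zero end slopes), mirrored across
  both axes, vessel center 0.0667 R₁ below the PVS midline, tapering to
  a minimum end height of R₁/4.5. The end condition was a genuinely open
  choice: not-a-knot gives an area ratio K = 1.511 and natural ends
  1.467, while zero-slope ends give K = 1.4828 *and* are the
  geometrically consistent choice — mirroring across the vertical axis
  at the first control point and closing onto the horizontal mirror at
  the last requires zero boundary slopes for a C¹ outline. K is
  independent of R₁ by construction.
* **Polynomial shape.** One least-squares line through the top boundary
  (uppermost PVS pixel per column, spanning both lobes — a single line
  even when the lobes are disconnected), and one quadratic per lobe
  through the bottom boundary (columns strictly outside the vessel
  circle, with a half-pixel margin so columns catching the sliver just
  above the vessel's widest point are not mistaken for lobe bottom; one
  robust re-fit pass drops gross outliers against the first fit).
  Derived measures per side: W from the vessel edge to the farthest
  column; H₁, H₂, H₃ as top-line minus bottom-quadratic heights at the
  vessel edge, midway, and the far end (H₂'s "midway" is the horizontal
  midpoint of W); H_C as the top-line height above the vessel top at the
  vessel-center column, negative when the lobes are disconnected. A side
  with fewer than 3 boundary columns is absent; both absent is an error.
  The synthetic generator parameterizes its ground truth with exactly
  this model, so noise-free recovery is exact up to rasterization.

Any fit can be exported as polygon rings by tracing the zero level of
its implicit signed field on a sub-pixel grid (default 8 points/µm; the
grid is offset by an irrational fraction of a step so contour lines
never coincide with straight boundary stretches). Rings follow even-odd
semantics: a concentric annulus is an outer ring plus a hole, a
disconnected shape is two rings.

Area ratios K divide by the fitted circle area πR₁² for the idealized
fits and by the segmented vessel area for segmentation-based K.

## Hydraulic resistance

Fully developed laminar flow in a straight channel of constant cross
section obeys `∇²u = −G/μ` with `u = 0` on the walls; the resistance per
unit length is `R = G/Q` with `Q = ∫u dA`, independent of the gradient
G. Defaults: μ = 7.058 × 10⁻⁴ Pa s (water at 36 °C) and G = 500 Pa/m for
the reported velocity profiles.

The solver discretizes the Poisson problem on a regular grid with
boundary-fitted (Shortley–Weller) stencils: where a stencil arm crosses
the boundary, it is shortened to the actual crossing — computed exactly
for polygon domains and by 40-step bisection of the signed field for
analytic shapes — which restores second-order accuracy on smooth
boundaries. The grid origin is offset by an irrational fraction of the
step so nodes never sit exactly on straight edges. Refinement starts at
20 divisions across the domain and halves the step until a circle with
the same node density per equal-area radius is accurate to better than
1% against `8μ/(πa⁴)` (the calibration is cached by node density). This
is a deliberate substitution of scheme — a triangular-mesh FEM would do
the same job — while keeping the same accuracy criterion; against closed
forms the solver achieves ~0.02% (circle) and well under 1% (concentric
annulus, rectangle series solution) at the default setting. Because the
step scales with the domain, geometric scaling of a cross section
reproduces the exact `R ∝ area⁻²` law.

Masks become flow domains by one-pixel erosion (3 × 3 box, with the mask
padded first so erosion is correct at the image border) and 0.5-level
contour tracing; disconnected lobes are separate rings solved on the
same grid, so their flow rates add as parallel channels. A mask whose
erosion leaves fewer than 4 pixels is rejected as degenerate. Segment
totals treat sections as resistors in series: mean per-unit-length
resistance times segment length.

The optimal concentric elliptical annulus is the closed-form
approximation `R = 6.67 μ K^−1.96 / R₁⁴`. The widely quoted form with
the fourth power outside the whole bracket is dimensionally inconsistent
and misses the reference value of 8.7 × 10¹⁵ Pa s/m⁴ at K = 1.4,
R₁ = 23 µm by many orders of magnitude; both readings are exposed
(`form = "printed"`), with the consistent one as the default.

## Distribution statistics

Quartiles use linear interpolation between order statistics (type 7 —
the convention had to be fixed; it is R's default and the most common).
Outliers are Tukey-fenced at 1.5 IQR. The distribution peak is the
center of the most probable of 20 equal-width bins spanning the
non-outlier range (configurable to the full range); ties break toward
the lower bin, and a degenerate range returns the common value.
Power-law and linear fits are ordinary least squares on transformed
data, with normal-theory 95% confidence intervals. Best-fit shares give
each section to the model whose metric is closest to the segmentation's,
splitting exact ties equally. The quintessential shape rebuilds a
polynomial cross section from the distribution peaks of H₁, H₂, H₃, H_C,
the short and long widths, and R₁ (short side drawn on the left).

## The synthetic test bed

The generator renders a vessel axis that is quadratic in y(x) and z(x)
(curvature defaults 2 × 10⁻⁴ and 1 × 10⁻⁴ µm⁻¹ — a few micrometers of
bow over a field of view), with a circular lumen and a two-lobed
polynomial PVS in the local normal frame. Voxels are assigned by exact
projection onto the axis (Newton iteration on the orthogonality
condition), so the ground-truth masks are the exact rasterization of the
geometry, and `groundTruthSections()` returns the exact shape at any
arclength. Default shape parameters sit at the peak values of the
published per-section distributions (R₁ 20.8, H₁ 39.5, H₂ 18.6, H₃ 9.37,
H_C 0.799, widths 22.3 and 42.1 µm) in a 512 × 512 × 150 voxel volume;
profiles can modulate sinusoidally along the segment.

The imaging model is deliberately simple and its parameters are
assumptions, not measurements: intensity = constant detector offset
(150 counts) + (autofluorescence 100 + tracer signal 12000/9000 counts)
× exp(−depth/150 µm) × a shadow factor of 0.5 for voxels below any lumen
voxel in their column; separable Gaussian blur of σ = (0.5, 0.5, 1.5) µm;
additive read noise (σ = 100) plus a signal-dependent term 1.5·√I;
16-bit clipping. Splitting the background into an unattenuated detector
offset and an attenuated autofluorescence term matters: it keeps the
shadow edge invisible in deep, structureless planes, as in real data
where the background is mostly dark counts. An optional cardiac jitter
perturbs the rendered lumen radius by up to ±2% of the diameter per
plane without touching the ground truth. The `"clean"` preset disables
every degradation (and the offset), which makes half-maximum
thresholding — and the full segmentation path — reproduce the ground
truth exactly.

What the synthetic tests establish: that every stage implements its
stated rule, that the chain is internally consistent (exact recovery
under degenerate imaging; Dice ≥ 0.85 under the default degradations, on
par with reported inter-operator agreement), and that parameter recovery
is sub-pixel under the published parameter ranges. What they do not
establish: performance on real stacks, whose noise is not Gaussian,
whose attenuation is not exponential, whose vessels branch and whose
PVSs are not exactly polynomial. The generator emulates one vessel, no
motion beyond the optional jitter, and no scattering physics.

## Problem sizes and determinism

The test suite exercises the full chain on a 160 × 120 × 64 voxel volume
with R₁ = 8 µm (the same proportions as the full-scale defaults),
renders 50 single sections at production scale for parameter recovery,
and calibrates the flow solver on circles of 10–40 µm; these sizes keep
the default suite fast while leaving every algorithmic path identical to
a full-scale run. All randomness flows through explicit seeds
(`withr::with_seed`), and a pipeline run with a fixed seed is
bit-reproducible, including its on-disk artifacts.

## Known limitations

* Single, non-branching pial segments only; the centroid-based
  centerline and two-component PVS cleanup assume this topology.
* The three-piece threshold refinement assumes signal decreases with
  depth; inverted contrast would need the Mean + SD path.
* Resistance assumes straight-channel, quasi-steady flow; axial shape
  variation and wall motion (order-10% effects) and nonlinear unsteady
  terms (order-1% at pial Womersley numbers) are ignored.
* The mesh-refinement criterion calibrates on an equal-area circle; very
  thin lobes may be locally under-resolved at the accepted step even
  though the calibration passes, exactly as with the analogous
  triangular-mesh criterion.
* The quantile, histogram-range, and tie-breaking conventions are fixed
  choices among defensible alternatives; all are configurable or
  documented where they affect reported numbers.
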