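# pvsmorph

Morphometry and hydraulic resistance of pial perivascular spaces (PVS)
from in vivo two-photon microscopy.

Pial arteries on the brain surface are surrounded by CSF-filled
perivascular spaces that act as low-resistance channels for cerebrospinal
fluid. How much CSF they can carry depends on the size *and shape* of
their cross section. `pvsmorph` implements a complete, tested analysis
chain for two-channel 3D fluorescence stacks (a vascular tracer channel
and a CSF tracer channel):

1. **Segmentation** — depth-varying intensity thresholds (an automated
   Edge Finder based on per-plane gradient ridges, a Mean + SD threshold,
   and a per-plane Otsu comparator), refined to a three-piece
   constant/ramp/constant profile, followed by small-region removal,
   largest-component selection, hole filling, and vessel/PVS overlap
   resolution. Validation metrics: intersection-over-union against a
   high-SNR 2D reference (with rigid 2D-to-3D registration) and the 3D
   Dice coefficient `DC = 2|A∩B| / (|A|+|B|)`.
2. **Centerline-normal cross sections** — isotropic resampling, vessel
   centerline extraction and quadratic smoothing, orthonormal section
   frames at ~0.8 µm arclength spacing, oblique resampling of both masks,
   and the edge-exclusion rule (sections closer to the volume edge than
   the median PVS width / 2.5 are dropped).
3. **Idealized cross-section geometries** — a circle fit to the vessel
   (convex-hull exclusion of the unreliable bottom edge), an elliptical
   annulus sharing the PVS centroid and second central moments, a
   canonical two-lobed spline geometry that scales with the vessel radius
   only (PVS-to-vessel area ratio K ≈ 1.48 by construction), and a
   two-lobed polynomial geometry (one top line, one bottom quadratic per
   lobe) parameterized by the widths W and heights H₁, H₂, H₃, H_C.
4. **Hydraulic resistance** — fully developed Poiseuille flow on each
   cross section: `∇²u = −G/μ` with no-slip walls, `R = G/Q` per unit
   length, solved on a boundary-fitted finite-difference grid refined
   until the equal-area circle is accurate to < 1%; closed forms for the
   circle (`8μ/πa⁴`), the concentric circular annulus, and the optimal
   concentric elliptical annulus `R = 6.67 μ K^−1.96 / R₁⁴`; segment
   totals as resistors in series.
5. **Distribution statistics** — 20-bin histogram peaks, type-7
   quartiles, Tukey outlier fences, PVS-vs-vessel-area linear fits,
   log–log power-law fits of resistance against area with confidence
   intervals, best-fit model shares, and the quintessential
   (distribution-peak) PVS shape.

Because in vivo stacks are not required, the package ships a
**synthetic-stack generator**: a gently curved vessel tube with a
two-lobed PVS rendered with depth attenuation, a shadow cone beneath the
lumen, optical blur, and mixed Gaussian/shot noise — together with exact
ground-truth masks and shape parameters, so every stage is tested against
a known answer.

## Worked example

```r
library(pvsmorph)

## the representative polynomial cross-section (peak parameter values)
sh <- polynomialShape(r1 = 20.8, wLeft = 22.3, wRight = 42.1,
                      h1 = 39.5, h2 = 18.6, h3 = 9.37, hC = 0.799)
sh
#> PolynomialShape: R1 = 20.80 um, HC = 0.799 um
#>   left : W =  22.30  H1 =  39.50  H2 =  18.60  H3 =   9.37 um
#>   right: W =  42.10  H1 =  39.50  H2 =  18.60  H3 =   9.37 um
areaRatio(sh)
#> [1] 1.134639

## hydraulic resistance of that cross section (water at 36 C, 500 Pa/m)
solvePoiseuille(sh)
#> FlowSolution: R = 2.527e+16 Pa s/m^4 (Q = 1.98e-14 m^3/s at 500 Pa/m; ...)

## the canonical spline geometry has a fixed area ratio
areaRatio(splineShape(20.8))
#> [1] 1.482817

## optimal concentric elliptical annulus at K = 1.4, R1 = 23 um
optimalAnnulusResistance(1.4, 23)
#> [1] 8.699318e+15
```

`areaRatio(sh)` is the PVS-to-vessel area ratio K (PVS area over the
vessel circle area); the resistance is per unit channel length, so a
100 µm segment of this cross section resists `R × 10⁻⁴ m`.

A full synthetic run — simulate, segment, slice, fit, solve, summarize —
is one call:

```r
res <- runPipeline(pipelineConfig(preset = "realistic", seed = 1,
                                  outDir = "pvs-out"))
res$dice          # segmentation quality against the known ground truth
res$areaRatioStats  # K distribution summaries per model
```

The same stages are available from a shell via the thin wrapper
`inst/scripts/pvsmorph-cli.R` (`simulate`, `segment`, `sections`, `fit`,
`resistance`, `stats`, `run-all`).

## Scope

The package analyzes single, non-branching pial (surface) vessel
segments. Penetrating and venous PVSs, bifurcation regions, unsteady
(Womersley) flow, and learning-based segmentation are out of scope. See
the methods vignette (`vignettes/pvsmorph-methods.Rmd`) for the model
assumptions, parameter choices, and known limitations.
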