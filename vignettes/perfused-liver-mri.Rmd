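---
title: "Quantitative MRI of machine-perfused livers: models, parameters and phantoms"
author: "perfuseMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI of machine-perfused livers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfuseMRI)
```

## The analysis problem

Machine perfusion keeps an explanted organ viable outside the body by
circulating oxygenated blood through its vasculature. Imaging such an
organ in a clinical MRI scanner gives access to three complementary
readouts: vascular architecture from T2-weighted volumes, tissue
microstructure from diffusion-weighted imaging (DWI), and flow from
dynamic contrast-enhanced (DCE) series after a gadolinium bolus is
injected into the inflow line. Preservation quality is verified
separately by scoring needle biopsies on a histopathology rubric.

This package implements that entire analysis chain as plain functions on
two data structures — `ImageVolume` (a 3D/4D scalar grid with voxel
spacing in mm and, for time series, a frame interval in seconds) and
`SpatialGraph` (a vessel centerline network with per-point radii in mm) —
plus a synthetic phantom generator that makes every stage testable by
parameter recovery against analytic ground truth.

## Vessel graphs from binary masks

Segmentation is seeded region growing over an explicit intensity band
`[low, high]` (the interactive "magic wand" made reproducible), with
per-plane masks merged by voxel-wise union. The mask-to-graph protocol is
the standard five-step pipeline:

1. **Chamfer distance map.** Two-pass ⟨3, 4, 5⟩ chamfer transform over
   the 26-neighbourhood. The two-pass sweep is exact for chamfer metrics;
   the suite verifies equality with multi-source Dijkstra on the voxel
   graph. Out-of-grid voxels count as background. Distances convert to mm
   via the face weight and the face voxel size.
2. **Distance-ordered thinning.** Foreground voxels are eroded in
   increasing distance order; a voxel may only be removed if it is a
   (26, 6) simple point (removal preserves foreground 26-connectivity and
   background 6-connectivity locally) and not a line end (≤ 1 foreground
   neighbour). Naive endpoint-protected erosion eats free tube ends
   axially, so the implementation anchors ridge voxels: strict local
   maxima of the distance map after a deterministic tie-break
   perturbation (plateau centrality — the fraction of ≥-distance
   neighbours — plus an index hash, together under one chamfer unit).
   Plateau rims erode first, which keeps line ends centred on tube axes;
   anchors are isolated by construction, so a synchronous six-direction
   cleanup pass reduces any residual two-voxel-thick plateau to a 1-wide
   line. Terminal spurs shorter than the minimum end length (default 2
   voxels) are pruned. The reference implementation of this module in the
   original interactive software is proprietary; equivalence is claimed
   at the level of invariants (topology preservation, axis centring),
   not bit-exactness.
3. **Line tracing.** Skeleton voxels with ≠ 2 skeleton neighbours become
   nodes; maximal chains of 2-neighbour voxels become segment polylines
   in world mm; an isolated cycle receives one artificial degree-2 node.
4. **Smoothing.** Interior polyline points relax as
   `p ← p + 0.5 (mean(neighbours) − p) + 0.25 (p₀ − p)` for 10
   iterations with node positions fixed — a straight polyline is a fixed
   point, and `attach = 1, smoothing = 0` is the identity.
5. **Radii.** Each polyline point takes the chamfer distance at its voxel
   (the inscribed-ball radius), which is well defined even slightly
   off-axis.

A final cleanup collapses segments shorter than 1.5× the local endpoint
radius (floor: two voxels) whose ends are both branch points, and drops
equally short loops and terminal whiskers. Such segments lie inside the
junction's own inscribed ball and cannot be real vessels; without this
step, 26-connected thinning reliably leaves tiny cycles at bifurcations.
The factor 1.5 was chosen once against phantom trees (a sub-radius
threshold leaves split junctions; anything below ~2 behaves identically).

Morphometrics follow the field's definitions: tortuosity is curved over
chord length (1 for a closed loop by convention), terminal nodes have
degree 1, branching nodes degree ≥ 3, degree-2 cycle markers are excluded
from both counts, and the coordination number is averaged over branching
nodes only. Vessel volume is reported both ways — frustum sums over the
radius-annotated graph and voxel-count volume of the mask — since either
convention is defensible and they differ when a single wide branch
dominates.

## ADC mapping

The monoexponential model `S = S₀ exp(−D·b)` is fitted per voxel and per
diffusion direction by log-linear least squares (`D = −slope`), which is
closed-form, deterministic and exact on noise-free input; a voxel with
any non-positive signal is flagged invalid rather than zero-filled. The
ADC is the arithmetic mean of the per-direction D maps — deliberately
*not* a tensor fit, matching the three-orthogonal-direction acquisition.
Parenchymal statistics exclude background (threshold on the lowest-b
volume, default 10 % of its 99th-percentile maximum — the protocol's
"subtract the background" made operational) and vessel voxels (mask
resampled nearest-neighbour to stay binary). Units are mm²/s throughout;
the value 0.55 × 10⁻³ used in defaults and phantoms is treated as mm²/s
(source material prints s/mm², which we read as a typo for the standard
ADC unit).

## DCE analysis

Enhancement is signal minus the mean of the baseline frames — no
concentration conversion is attempted, since no relaxivity calibration is
part of the workflow. TTP is the *first* frame attaining the maximal
enhancement (deterministic on plateaus, and equal to the arrival frame
under the phantom's step kernel). The bolus front along a centerline path
is the farthest point whose enhancement has reached half of that point's
eventual maximum ("half-max arrival"; the threshold is a parameter);
front distance is forced non-decreasing. Velocity is the regression slope
of front distance on time restricted to the transit window — plateau
frames after the front reaches the end of the path would bias the slope
toward zero, and the attainment frame itself is dropped when enough
moving samples remain because the true crossing time lies somewhere
inside the preceding frame interval. Flow uses `Q = ¼ π d² v` with the
diameter taken as twice the graph radius at the measurement location.

## The phantom world, and what a green test does not establish

`generateVesselTree()` grows a binary bifurcating tree: one root segment,
then two children per tip deviating ±37° from the parent direction in a
randomly oriented plane. Radii taper geometrically per generation;
tortuosity comes from a half-sine lateral displacement with analytic arc
length (the test oracle integrates it numerically). Default stated world:
0.83 mm isotropic voxels, root radius 4 mm, decay 0.75 over 4
generations (finest radius 1.69 mm), 16 mm chords, 0.8 mm amplitude —
giving resolvable branches, pure bifurcations, and near-1 tortuosity, the
regime the real organs occupy. DWI noise is Gaussian on two quadrature
channels followed by magnitude (Rician); the DCE kernel is step-and-hold
by default so TTP ties equal arrival frames, with a gamma-variate kernel
available for rise-and-fall realism (real enhancement curves fall after
the peak; which shape real curves follow is not specified by the
workflow, so the step kernel is a modelling choice, not a claim).
Histology scores split between floor and ceiling of the stated mean with
probability equal to the fractional part — the expectation is exactly the
stated mean — plus optional integer jitter clamped to 0..3; the clamping
biases means toward the middle of the scale when `dispersion > 0`, which
the tests avoid by checking mean recovery at `dispersion = 0`.

The phantoms deliberately omit: dual-inflow haemodynamics, pulsatile
flow, susceptibility and motion artefacts, partial-volume fading at
sub-voxel radii, and anatomically realistic branching asymmetry. A green
recovery test therefore establishes the correctness of the *computation*
(segmentation → graph → metrics; signal model → fit; front → velocity),
not robustness to those physical effects.

## Numerical choices and degenerate inputs

* Ties in thinning removal order break by voxel index; all generators
  route randomness through one explicit seed, so every pipeline output is
  reproducible bit-for-bit (floating artifacts to 1e-9).
* Resampling uses the Mitchell–Netravali cubic at B = C = 1/3 (the
  published "Mitchell" setting; the protocol names only the algorithm),
  with border weights renormalized so constants are reproduced exactly.
  All axes are resampled if anisotropic; the z-only case is the special
  case. The rule linking field of view to target spacing is not specified
  upstream, so the target is a configuration value.
* Necrosis percentages exactly at a rubric boundary (10 %, 30 %) take the
  higher score; multiple fields per biopsy score as their maximum.
* An empty mask yields an all-zero distance map with a warning; a closed
  loop traces to a single artificial node; a constant DCE voxel is
  flagged invalid rather than assigned TTP 0; radii of off-mask polyline
  points are 0 with a warning.
* The independent t test uses the pooled-variance form (with Shapiro–Wilk
  and Brown–Forsythe Levene diagnostics alongside); with zero pooled
  variance and equal means it reports t = 0, p = 1. The group comparison
  is a reporting convenience — no claim is made of reproducing any
  specific published p-value, since biopsy-level scores are not public.

## Known limitations

Skeletons retract by roughly one radius at free tube ends (inherent to
homotopic thinning), so terminal segments are slightly short; chamfer
⟨3, 4, 5⟩ radii carry a few percent of systematic overestimate relative
to Euclidean distance; junction positions after artifact collapse are
accurate only to about the junction radius; and the bolus-front velocity
is quantized by the frame interval when the path is short relative to
`v × Δt`. All of these are visible — and bounded — in the recovery tests.
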