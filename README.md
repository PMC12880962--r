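# perfuseMRI

Quantitative MRI analysis of whole organs under ex vivo machine perfusion,
built for the workflow in which an explanted liver is perfused with
oxygenated blood inside a clinical scanner and assessed with structural
(T2-weighted), diffusion-weighted (DWI) and dynamic contrast-enhanced
(DCE) sequences, alongside histopathological scoring of biopsies. The
package is aimed at imaging scientists who want every step of that
analysis as reproducible, testable code rather than a chain of interactive
tools.

## What it computes

**Vessel morphometrics.** A binary vessel segmentation (seeded region
growing over an intensity band, per-plane masks merged by union) is turned
into a centerline *spatial graph* by the classic five-step protocol:

1. 26-neighbourhood chamfer distance map (weights ⟨3, 4, 5⟩),
2. distance-ordered topology-preserving thinning (minimum end length 2),
3. line tracing (voxels with ≠ 2 skeleton neighbours become nodes),
4. polyline smoothing (10 iterations, smoothing 0.5, attach 0.25),
5. per-point radii from the chamfer map (inscribed-ball radius).

From the graph: total vessel length and volume, branching/terminal node
counts, coordination numbers, and per-segment curved length `L_c`, chord
length `L_s`, tortuosity `τ = L_c / L_s`, mean radius and frustum volume
`Σ π r̄ᵢ² δlᵢ`.

**ADC mapping.** Voxel-wise log-linear fit of the monoexponential model
`S = S₀ exp(−D·b)` over b = 90, 500, 1500, 2000 s/mm², fitted per
diffusion direction and averaged; parenchymal statistics after background
thresholding and vessel masking.

**DCE analysis.** Voxel-wise time-to-peak (TTP) maps (first maximum of
baseline-subtracted enhancement), ROI enhancement curves with a min/max
envelope over repeats, bolus-front tracking along a centerline path
(half-max arrival), velocity by regression of front distance on time, and
volumetric flow `Q = ¼ π d² v` (d in cm, v in cm/min, Q in mL/min).

**Histology scoring.** The four-category rubric (neutrophil infiltration,
hepatocyte necrosis, sinusoidal congestion, sinusoidal oedema; each 0–3)
with the 0–12 composite, group summaries, and a two-sample t test with
Shapiro–Wilk and Levene diagnostics.

**Synthetic phantoms.** Every stage is testable by parameter recovery: a
seeded generator grows bifurcating vessel trees with known radii and
analytic tortuosity, rasterizes them as capsule unions, and simulates
T2-like contrast, multi-b DWI (Rician noise), a contrast bolus advancing
along the tree, and biopsy-level histology tables. Minimal NIfTI-1 I/O is
built in.

## Worked example

```r
library(perfuseMRI)

spec <- PhantomSpec(c(140, 140, 120), spacing = rep(0.83, 3), treeDepth = 4,
                    rootRadius = 4, radiusDecay = 0.75, segmentLength = 16,
                    tortuosityAmplitude = 0.8, seed = 1)
truth <- generateVesselTree(spec)
mask  <- rasterizeTree(truth, spec)
graph <- extractVesselGraph(mask)
networkSummary(graph)
```

```
Vascular network summary
  total length  238.2 mm, total volume 3570.7 mm^3
  nodes: 7 branching, 9 terminal (terminal fraction 0.56)
  mean coordination number 3.00
  medians: segment length 15.30 mm, radius 1.78 mm, tortuosity 1.019
```

The phantom was grown with 7 bifurcations and 9 terminals; the recovered
graph matches that topology exactly, every branch point is a bifurcation
(coordination 3), and the median radius and tortuosity recover the
generator's ground truth (median radius 1.69 mm, tortuosity ≈ 1.006)
within the documented tolerances. A full configured run —

```r
res <- runPipeline(list(output_dir = "run1", seed = 1))
```

— writes the phantom volumes (NIfTI), the ground-truth and recovered
graphs (JSON), per-segment CSV, morphometrics JSON, ADC map and
parenchymal statistics, TTP map, bolus-front trajectory and flow JSON,
and the simulated histology table with its group comparison. A thin CLI
(`inst/scripts/perfusemri`) exposes `run`, `morphometrics` and
`histology` subcommands.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end phantom analysis from scratch under
the given seed — tree generation, rasterization, segmentation, graph
extraction, morphometrics, ADC mapping, DCE flow estimation and histology
simulation — printing a short summary and writing the JSON report to
`--out`.
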