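---
title: "Dose-level discretization, Gaussian reconstruction and plan evaluation"
author: "doselevels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-level discretization, Gaussian reconstruction and plan evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doselevels)
```

## The model

`doselevels` supports a dose-prediction strategy that treats 3D dose
prediction as semantic segmentation. A planned dose distribution
$D_{GT}(x)$ (Gy) on a regular voxel grid is first normalized to relative
dose $d(x) = 100\,D_{GT}(x)/D_{Rx}$, where $D_{Rx}$ is the per-fraction
CTV prescription, and restricted to $[0, 120]\%$. With an isodose
interval $i$ (percent) the relative range is partitioned into
$T = 120/i$ isodose volumes; level $t \ge 1$ covers
$[(t-\tfrac12)i,\,(t+\tfrac12)i)$ and label 0 (background) covers
$[0, \tfrac{i}{2})$. A segmentation network is trained to predict these
labels from two channels:

* the **avoidance image**: each voxel takes the maximum clinical-priority
  weight among the structures containing it — heart, ribs and skin 1,
  whole breast 0.5, body 0.1, elsewhere 0;
* the **normalized prescribed dose**: 1 inside the CTV, the prescription
  ratio (PTV-Rx / CTV-Rx) in the PTV$-$CTV ring, 0 outside the PTV.

A predicted label map is converted back to a continuous dose by
bin-center reconstruction $P(y) = t(y)\, i$ followed by convolution with
an isotropic 3D Gaussian

$$D(x) = (K_\sigma \ast P)(x), \qquad
K_\sigma(x) = \frac{1}{(2\pi)^{3/2}\sigma^3}
  \exp\!\left(-\frac{\lVert x\rVert^2}{2\sigma^2}\right),$$

and scaling by $D_{Rx}/100$. Predictions are scored against the
reference plan with cumulative isodose Dice coefficients, voxel-wise
MAPE, DVH metrics with paired Wilcoxon signed-rank testing, and global
gamma passing rates.

The package implements everything except the network itself, which is a
pluggable black box: in-process as any function
`DoseLevelMap -> DoseLevelMap`, or out-of-process through the
nnU-Net-style dataset export/import contract.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `intervalPercent` ($i$) | 5 (2 supported throughout) | % of $D_{Rx}$ | Sets $T = 120/i$ classes; smaller $i$ keeps more dose detail at the price of more output channels. |
| `sigmaMm` ($\sigma$) | 2 | mm | Matches the 2 mm grid resolution; larger values blur real gradients, smaller ones leave staircase artifacts. |
| `truncationRadiusSigmas` | 4 | $\sigma$ | Kernel support; at 4$\sigma$ the discarded tail mass is $<10^{-4}$, and the sampled kernel is renormalized to exact unit sum anyway. |
| `boundaryMode` | reflect | — | Mirror-with-edge padding; `nearest` and `zero` available. Under reflect/nearest the output provably stays inside the input range. |
| avoidance weights | 1 / 1 / 1 / 0.5 / 0.1 / 0 | — | Heart, ribs, skin / breast / body / background, mirroring planning-objective priorities; configurable per run. |
| gamma `doseDiffPercent`/`dtaMm` | 3 / 2 and 3 / 1 | % , mm | The two criteria reported for plan agreement. |
| `searchStepMm` | dta/10 | mm | Sub-voxel interpolation step; required because a 1 mm DTA is finer than the 2 mm voxels. |
| `lowDoseCutoffPercent` | 0 | % of $D_{norm}$ | Full-volume gamma by default. |
| hotspot screen | 102 | % of $D_{Rx}$ | Cases whose maximum dose strictly exceeds this are excluded from datasets. |

## Numerical conventions

* **Bin edges.** The nominal level ranges overlap at their endpoints; a
  partition needs a tie rule. We use lower-inclusive bins with ties at
  $(t-\tfrac12)i$ rounding up (`floor(d/i + 0.5)`), $d < i/2 \to 0$ and
  $d = 120 \to T$. Consequently the smallest representable nonzero
  relative dose is $i/2$: 2.5% at $i=5$, 1% at $i=2$.
* **Normalization reference.** Relative dose, MAPE and global gamma all
  normalize by the CTV prescription; dose above 120% of it is clipped
  before discretization (moot for screened cases, which cannot exceed
  102%).
* **Reconstruction scalar.** The smoother convolves the bin-center
  scalar field rather than per-class probability channels; centers
  minimize the worst-case quantization error ($i/2$ relative points,
  an exact bound verified by property tests).
* **Kernel discretization.** $K_\sigma$ is sampled at voxel centers,
  truncated on a cube of half-width $\lceil 4\sigma/s\rceil$ voxels and
  renormalized; the 3D convolution is computed as three separable 1D
  passes, which is exactly the sampled 3D kernel for a Gaussian.
  Anisotropic grids are rejected rather than silently approximated.
* **Dx% rank convention.** ROI doses are sorted descending and the value
  at rank $\lceil x n/100 \rceil$ returned, with no interpolation; this
  guarantees at least $x\%$ of the ROI receives at least the returned
  dose and is convention-stable across platforms.
* **Wilcoxon details.** Two-sided signed-rank via `stats::wilcox.test`
  on the nonzero paired differences (zeros dropped), exact distribution
  for $\le 25$ informative pairs and normal approximation with
  continuity correction above; fewer than 5 pairs is reported as
  skipped, all-zero differences as $p = 1$.
* **Gamma search space.** The gamma minimum is taken over a fixed,
  deterministic search space: a cubic sub-grid of step `searchStepMm`
  intersected with a sphere of radius `searchRadiusFactor` $\times$ dta
  (default 3 dta). A fixed space makes the compiled implementation and
  the brute-force oracle in the test suite minimize over *identical*
  candidate sets, so they can be compared to $10^{-9}$. The compiled
  loop visits offsets in increasing distance and stops once the distance
  term alone reaches the current best — a pure optimization that cannot
  change the minimum. Voxels whose true gamma exceeds the radius factor
  are reported at the truncated minimum; since that is still $> 1$, the
  passing rate is unaffected. Search positions outside the evaluated
  volume are skipped; the zero offset is always available.
* **Degenerate inputs.** Two empty masks have DSC 1 by convention; an
  empty ROI, a missing body/CTV/PTV mask, a non-divisor interval, dose
  outside $[0,120]\%$, and anisotropy where isotropy is assumed all
  raise typed errors rather than propagating nonsense.

## The synthetic phantom

`generatePhantom()` emulates the preprocessing product of a
prone-breast stereotactic cohort on the standard grid (128³ voxels at
2 mm): a hemispherical breast of radius 60 mm on a chest-wall slab,
nested spherical GTV/CTV/PTV (10 mm radius + 5 mm + 3 mm margins), a
3 mm skin shell, an 8 mm rib shell behind the wall and a heart ellipsoid
beyond the ribs. The dose model is analytic: a plateau inside the PTV
with Gaussian radial falloff of scale 8 mm outside, a small GTV hotspot
(1% by default, capped so the 102% screen always passes), and a smooth
seeded noise field of 0.3% amplitude. The field is rescaled so
D95%(CTV) equals the prescription (8 Gy CTV / 6 Gy PTV per fraction by
default, the institutional guideline geometry), the only calibration
applied.

These defaults were chosen once as a realistic stand-in for the study
conditions and are not tuned per test. What the phantom does *not*
emulate: CT texture, plan-to-plan optimizer variability, multi-fraction
prescription changes within a patient, true Co-60 transport (no
build-up, scatter tails or beam channels). Tests that pass on the
phantom therefore validate the geometry, discretization and metric
code paths — not dosimetric realism, and not the accuracy of any real
segmentation network.

Two mock predictors bracket backend behavior: the identity oracle
(perfect segmentation; DSC 1 everywhere, unsmoothed MAPE bounded by
$i/2$) and a boundary perturbed predictor that flips voxels adjacent to
level boundaries with a set probability — errors concentrate at steep
dose gradients, which is where segmentation networks actually fail.

## Design choices that were genuinely open

* **Overlap precedence in the avoidance image** is maximum weight (a
  skin voxel inside the breast is 1), the natural reading of
  "highest priority wins"; targets carry no weight of their own and
  inherit the tissue they sit in.
* **Interpolants** for resampling are trilinear for scalar fields and
  nearest-neighbor for masks — standard practice; masks stay strictly
  binary.
* **Crop convention**: the reference structure's voxel-index centroid,
  rounded down, lands at output index `size %/% 2`; out-of-window
  regions are zero-padded (dose and anatomy are absent outside the
  scanned extent) and the origin is updated so physical coordinates are
  preserved.
* **Fixed gamma search radius** instead of an adaptively growing one —
  see the numerical conventions above; determinism and oracle
  comparability outweigh the marginal extra work, and the early-exit
  recovers almost all of the speed.
* **Background as a class**: the dataset descriptor lists $T+1$ labels
  (background + levels) while the backend's output-channel count is
  conventionally quoted as $T$; `manifestClassCounts()` exposes both to
  avoid off-by-one confusion.

## Problem sizes in the test suite

The property suites run at sizes chosen to keep the full check fast on
one CPU while still exercising every code path: 48³ phantoms for
pipeline-level tests, 12³ volumes against the exhaustive brute-force
gamma oracle (with search radius factor 1.5), 32³ random fields for the
quantization bound, and a single 128³ phantom for the end-to-end
discretize-at-2% / smooth-at-2 mm round trip, which achieves a 3%/2 mm
gamma passing rate of at least 99% against the analytic dose.

## Known limitations

* Global gamma only; local-normalization gamma is out of scope.
* Isotropic smoothing only; anisotropic grids must be resampled first.
* The gamma value (not the pass/fail decision) is truncated at the
  search radius factor for badly failing voxels.
* DVH curves are not modeled beyond the Dx% metrics.
* The phantom's limitations listed above: quantitative results on it do
  not transfer to clinical cohorts, which require real plans and a
  trained backend.
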