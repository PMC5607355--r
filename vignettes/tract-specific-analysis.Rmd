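---
title: "Tract-specific analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract-specific analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractsheet)
```

This vignette documents the scientific model behind `tractsheet`, the
parameters that matter, the numerical choices made where the method leaves
room, and what the synthetic phantoms do and do not establish about real
data.

## The tract model

A sheet-like white-matter tract is represented by a **medial surface**: a
triangulated mid-surface with, at every vertex $v$,

* a unit normal $n(v)$ pointing across the sheet's thin direction, and
* a radius $R(v) > 0$, the radius of the maximal sphere inscribed in the
  tract boundary and centred at $v$, so that $v \pm R(v)\,n(v)$ lies on the
  boundary.

The surface simultaneously encodes the skeleton (for statistics), the local
thickness (via $R$) and the boundary (for the projection search). Tubular
structures (fornix-like or cingulum-like bundles) have a medial locus that
degenerates to a curve; the model is deliberately not applicable to them and
`extract_medial_surface()` rejects such masks with an
`ill_suited_geometry` error (operationalized as: the second tangential
extent of the medial point cloud must exceed 3 voxels).

## Pipeline stages and their parameters

### FACT tractography — `fact_track()`

Deterministic fibre assignment by continuous tracking: within each voxel the
path follows that voxel's principal eigenvector (no interpolation) to the
voxel face, computed by exact parametric ray–box intersection with a
$10^{-6}$-voxel nudge across faces. One bidirectional streamline is seeded
per voxel at or above the FA threshold.

| parameter | default | meaning |
|---|---|---|
| `fa_threshold` | 0.1 | seed and propagation floor (appropriate for unmyelinated neonatal white matter; adult studies typically use 0.2) |
| `angle_threshold_deg` | 45 | maximum turning between successive segments |
| `max_steps` | 2000 | guard against pathological loops |

The eigenvector sign is chosen to minimise turning relative to the incoming
direction; at a perfectly perpendicular interface (a 90° turn with a
threshold above 90°) the tie is resolved toward the stored eigenvector
orientation, which is itself canonicalized (largest-magnitude component
positive) for reproducibility.

### Skeleton extraction — `extract_medial_surface()`

The discrete pipeline is: Euclidean distance transform $D$ of the tract mask
(exact, separable lower-envelope algorithm, anisotropic voxel sizes
honoured) → ridge detection → height-field triangulation → Laplacian
smoothing → normals and $R$.

Numerical choices, in order of consequence:

* **Ridge detection is gradient-directed.** Each in-mask voxel is assigned
  the lattice direction (of the 13 axis pairs in the 26-neighbourhood) best
  aligned with $\nabla D$, and is a ridge voxel iff $D$ is a local maximum
  one step either way along that direction. Where the gradient vanishes —
  exactly at a symmetric ridge — the global thin axis of the mask (smallest
  PCA component) is used instead. A global-axis-only detector was tried
  first and plateaued near 94% mid-surface accuracy on a 30°-rotated slab;
  the gradient-directed version reaches 100% there and, importantly, makes
  a tube's detected locus collapse to a curve so the tubularity rejection
  actually fires.
* **Sub-voxel refinement.** Each ridge voxel is shifted along its detection
  axis by the peak offset of the parabola through
  $(D(v-o), D(v), D(v+o))$, clamped to one voxel. This centres
  even-thickness slabs exactly on the half-voxel mid-plane.
* **Height-field triangulation.** The refined ridge cloud is expressed in
  its own PCA frame (two tangential axes, one thin axis), binned on a
  lattice at the mean voxel pitch anchored at the median point (a min-anchor
  is thrown off by border points), hole-filled from lattice neighbours
  (≤ 3 passes, ≥ 5 occupied 8-neighbours), and triangulated two triangles
  per complete cell. This yields an edge-manifold mesh by construction —
  the property the cluster adjacency graph and the VTK writer both rely on.
* **Smoothing acts on the height component only**, with
  `round(2 * smoothing_mm / voxel)` umbrella iterations at weight 0.5
  (`smoothing_mm` default 1 mm), so there is no tangential shrinkage.
* $R$ is the distance transform sampled (trilinearly) at each vertex;
  vertices with $R$ below a quarter voxel are pruned together with their
  triangles.

### Projection — `project_subject()`

For each vertex, tensors are looked up at $v + s\,n(v)$ for $s$ spanning
$[-R(v), R(v)]$ in steps of `sample_step_mm` (default: half the smallest
voxel edge), by nearest voxel, deduplicated per voxel, ordered by $|s|$.

* **max strategy** (the default used throughout): the sampled tensor with
  the highest FA supplies *all* requested metrics — one tensor per vertex
  per subject. FA ties break toward the smaller $|s|$, i.e. toward the
  tract core, which is deterministic and conservative.
* **mean strategy**: metrics are derived from the average of the sampled
  tensors. The averaging space is log-Euclidean by default (keeps the mean
  positive-definite and avoids the swelling artifact; eigenvalues are
  clamped at $10^{-12}$ inside the logarithm only), with Euclidean averaging
  available for sensitivity checks. Nothing hinges on this default in the
  shipped tests; it is exposed via `projection_params()`.

Vertices whose entire sample set is background (all-zero tensors) are
flagged missing and propagate as missing into the statistics — zeros would
bias the regression. Nearest-voxel (rather than interpolated) lookup
reflects the view that whole voxels are the candidates for projection;
sampling at half-voxel steps guarantees no candidate voxel along the normal
segment is skipped.

### The voxel-skeleton comparator — `fa_skeletonize()`, `tbss_project()`

This is an emulation of TBSS-style projection semantics for method
comparison, not a port of the reference implementation. A voxel joins the
skeleton iff its mean FA is at/above `fa_floor` and is a strict local
maximum along its search direction; the search direction is the lattice
direction of maximum FA change in the 3×3×3 neighbourhood. Two
underspecified points were resolved as follows:

* at a perfectly symmetric ridge the central difference vanishes in every
  direction; ties are broken toward the direction of steepest two-sided
  descent (the ridge's cross direction), then toward axis-aligned offsets.
  Without this rule a symmetric slab has no skeleton at all;
* projection steps one voxel at a time along the direction (both ways) and
  stops when a step would land strictly closer to a *different* skeleton
  voxel — the "skeleton distance map" stopping rule — or at
  `max_search_mm`.

`fa_floor` has no population-derived default; 0.2 is a conventional
placeholder and the phantom tests set it explicitly.

### Statistics — `fit_glm()`, `cluster_permutation_test()`

Ordinary least squares per vertex of the response on
`[1, predictor, nuisances]`, with $t = \hat\beta / SE(\hat\beta)$ on
$n - p$ degrees of freedom (QR-based; the tests verify against explicit
normal equations). Design choices:

* **Cluster-forming threshold**: default is the $t$ for uncorrected
  $p = 0.01$ at the design's df (0.005 per tail for two-sided contrasts).
  It is recorded in the result and overridable — a conventional default,
  made explicit because the choice materially affects cluster sizes.
* **Cluster statistic**: vertex count of connected components in the
  surface adjacency graph.
* **Permutation scheme**: Freedman–Lane — residuals from the nuisance-only
  model are permuted, the full model refitted, and the maximum cluster size
  recorded; corrected $p = (1 + \#\{\max_{perm} \ge size\}) / (1 + n_{perm})$
  with the identity permutation in the reference set, so $p \ge
  1/(n_{perm}+1)$. This keeps the test exact under nuisance signal, which
  the suite checks by simulation (empirical FWER within the binomial 95% CI
  of the nominal 5% over 200 null cohorts).
* **Perfect fits**: a zero-residual vertex would give $t = \infty$; the
  statistic is capped at $10^6$ as a sentinel so downstream thresholding
  stays finite.
* **Missing data**: a vertex is analysed only if at least 90% of subjects
  (and never fewer than $p + 3$) observe it; within the permutation test,
  only complete vertices enter, so the degrees of freedom never vary
  silently inside the null distribution.

### Evaluation — `dice()`, `bhattacharyya_distance()`, `wilcoxon_signed_rank()`

Dice is $2|A\cap B|/(|A|+|B|)$; per-subject summaries use the median over
all other subjects. FA distributions are compared as normalized equal-width
histograms (default 100 bins on $[0,1]$ — fine enough for tracts of
$10^3$–$10^4$ voxels; the bin count is recorded in every report because
$D_B$ depends on it) via $D_B = -\ln\sum_i \sqrt{p_i q_i}$. The Wilcoxon
signed-rank test drops zero differences (reporting the count), enumerates
the exact null through a convolution over doubled midranks for $n \le 25$
(exact under ties), and uses the normal approximation with tie and
continuity corrections above. Native-space reference values for the
projection comparison are the FA values at the voxels visited by the
selected streamlines.

## The synthetic generators

`make_sheet_phantom()` builds a sheet with mid-surface
$z = z_0 + a\sin(kx)$, half-thickness $t$ along the local normal, tensors
axially symmetric with the principal axis tangent to the sheet, FA falling
off quadratically from `peak_fa` at the mid-surface, and near-isotropic
surround. Defaults emulate neonatal tissue: 2 mm voxels, $t = 5$ mm, peak
FA 0.55, MD $1.2\times10^{-3}$ mm²/s — generator conveniences, all
config-exposed. An optional distractor plants a one-voxel high-FA layer a
configurable offset beyond the upper boundary; it is the device that
demonstrates the boundary-stopping difference between the surface projection
(never selects it) and the voxel-skeleton search (selects it when it falls
inside the search zone).

`make_cohort()` draws gestational age at birth uniformly in 24–32.9 weeks
and post-menstrual age at scan uniformly in 38.6–47.1 weeks — the ranges of
a preterm cohort scanned at term-equivalent age; uniform rather than
empirical sampling is intentional, since only the ranges are borrowed. FA
maps are baseline + planted patch effect ($\beta$ per week of PMA on a
connected 50-vertex patch grown from the surface centroid) + a
subject-level random intercept + vertex noise. Defaults: baseline 0.35,
between-subject SD 0.02, vertex SD 0.03.

What the phantoms do **not** emulate: registration error (volumes are
already in template space by assumption), crossing fibres, spatially
correlated noise, Rician noise floors, or realistic whole-brain anatomy.
Passing the suite therefore shows the machinery is correct under its stated
assumptions — not that those assumptions hold in any given dataset.

## Problem sizes used by the shipped tests

The statistics checks run on a ~440-vertex skeleton: family-wise error
calibration uses 200 null cohorts of 20 subjects at 500 permutations;
power uses 50 cohorts of 30 subjects with a per-vertex effect size of
$d = 1.0$ on the 50-vertex patch. These sizes give stable Monte-Carlo
estimates (binomial 95% band of ±3 percentage points around the 5% level)
while keeping the full suite under two minutes on one CPU.

## Known limitations

* Tubular tracts are out of scope by design (rejected, not mis-modelled).
* The skeleton is built once in template space from the template tract
  mask; subjects never get individual skeletons, so subject-level
  morphology enters only through the projected values.
* The voxel-skeleton comparator reproduces projection semantics only; it
  does not reproduce any particular reference implementation's
  skeletonization code path, and threshold-free cluster enhancement is not
  implemented.
* FACT is the only tracking model (no probabilistic tracking, no tensor
  interpolation), matching its suitability for low-b single-shell data.
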