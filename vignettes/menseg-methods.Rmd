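---
title: "Segmenting meningioma from paired T1/T2 slices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting meningioma from paired T1/T2 slices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menseg)
```

## The problem

Meningioma is one of the few benign intracranial tumors; complete surgical
resection is curative, which puts a premium on accurate delineation of the
tumor margin. On non-contrast MR, meningioma is conspicuous mainly through
its high T2 signal, and — unlike most gliomas — it often sits at or near the
brain midline, where symmetry-based detection schemes fail. `menseg`
segments a meningioma from a single pair of co-registered, non-contrast
T1- and T2-weighted axial slices, with no training data and no contrast
agent, and evaluates the result against an expert mask with the
percent-match / correspondence-ratio metrics standard in this literature.

## The pipeline

`menseg()` chains five stages, each exported on its own.

**1. Joint intensity histogram.** Every pixel is an ordered pair
$x_k = (x_{k,T1}, x_{k,T2}) \in [0,255]^2$; a $256 \times 256$ table counts
the pixels in each intensity pair. All clustering happens on this
histogram: pixels sharing a bin are interchangeable, so clustering bins
weighted by their counts is mathematically identical to clustering pixels,
at a small fraction of the cost (a property the test suite verifies against
a per-pixel implementation).

**2. Fuzzy c-means over occupied bins.** Memberships $u_{ik} \in [0,1]$
with $\sum_i u_{ik} = 1$ are initialized uniformly at random and the
standard alternating updates are iterated: centers
$v_i = \sum_k w_k u_{ik}^m x_k / \sum_k w_k u_{ik}^m$, memberships
$u_{ik} = 1 / \sum_j (d_{ik}/d_{jk})^{2/(m-1)}$, objective
$J = \sum_k w_k \sum_i u_{ik}^m \lVert x_k - v_i \rVert^2$, stopping when
$|\Delta J| \le \varepsilon$. Defuzzification assigns each bin to its
cluster of maximal membership (ties to the lowest index), producing $c$
binary images that partition the slice.

The cluster count deliberately *over-segments*: with `c = 32` (the
default), brain tissue splits into many groups, but the tumor — compact and
isolated in the (T1, T2) plane — separates into a group of its own, which
the later rules can recognize. `c` is exposed to reproduce cluster-count
sweeps (10, 16, 24, 32, 40).

**3. Seeded region growing.** Defuzzified groups are noisy and fragmented.
For each non-empty group the largest connected component seeds a growth
process: any pixel adjacent to the region whose T1 *and* T2 intensities lie
within $k = 2$ standard deviations of the seed's channel means is merged,
until no qualifying neighbor remains. With frozen seed statistics this
fixpoint equals the union of connected components of (seed ∪ eligible
pixels) that touch the seed, which is how it is computed; a breadth-first
oracle in the tests confirms the equivalence.

The pipeline additionally recomputes the region statistics twice during
growth (`update_stats = 2`, as in confidence-connected region growing): a
defuzzified fragment is a *truncated* sample of its tissue's intensity
distribution, so its SD underestimates the tissue spread, and purely frozen
statistics leave grown regions porous — which would invert the solidity
rule's premise that tumor groups are compact. Two bounded recompute rounds
let each fragment consolidate into its full tissue region while termination
stays guaranteed. `grow_region()` itself defaults to frozen statistics
(`update_stats = 0`).

**4. Knowledge-based selection.** Four rules, in order, with every decision
recorded in an audit trace:

* *(a) Bounding box.* A tumor seldom exceeds half the brain's extent; a
  candidate whose tight box is taller than half *and* wider than half the
  brain box is eliminated (an `"or"` variant is available).
* *(b) Laterality.* T2 histograms of the left and right image halves
  (intensities ≥ 50; tumors are bright on T2) are compared by Pearson
  correlation. Correlation above 0.95 means symmetric halves — the tumor,
  if any, is at the *midline* and this rule abstains. Otherwise the bin of
  maximal histogram difference is the reference point and the side with the
  higher count there is the tumor side; candidates with a pixel majority on
  the other side are eliminated. This is what lets midline tumors survive
  schemes that would otherwise rely purely on asymmetry.
* *(c) Solidity.* Solidity = area / rasterized convex-hull area. Tumors are
  compact (solidity near 1), tissue remnants ragged. Candidates are split
  into high/low groups by 1-D agglomerative hierarchical clustering and the
  low group is dropped — a relative criterion, so no threshold is learned
  or tuned.
* *(d) Area.* The same split on pixel areas removes small noise remnants.

Survivors are merged by pixelwise OR. A semi-supervised variant replaces
(c)–(d) with explicit human-chosen candidate ids (`manual_select`).

**5. Morphological refinement.** The merged mask is eroded (disk of radius
1 by default) to detach residual neighboring tissue, the largest component
is kept — discarding the residue, which a bare opening would re-attach —
then dilated by the same element, and enclosed holes are filled. If erosion
annihilates the mask the pipeline falls back to hole filling alone.

## Evaluation

With a ground-truth mask, pixel counts TP/FP/FN/TN give

$$\mathrm{PM} = 100 \cdot \frac{TP}{GT}, \qquad
  \mathrm{CR} = \frac{TP - 0.5\,FP}{GT}, \qquad GT = TP + FN.$$

PM is sensitivity against the expert contour; CR additionally penalizes
false positives and goes negative when they dominate, so a high PM with a
poor CR flags an over-inclusive segmentation. `summarize_cases()` reports
mean ± sample SD over cases, and `paired_ttest()` compares two per-case
series. The package ships the published 29-case count table
(`study_counts_path()`); `recompute_metrics_table()` reproduces its printed
PM/CR values from the raw counts exactly to table precision.

## The phantom generator

No images are distributed with the underlying study, so the package
includes a synthetic head phantom (`phantom_spec()`, `generate_phantom()`)
that encodes the conditions the pipeline assumes, with a known tumor mask:

* a 256×256 8-bit slice pair: elliptical head on a zero (air) background,
  scalp ring (bright T1), thin dark skull rim, broad gray/white matter
  compartments, CSF-filled lateral ventricles shaped as concave crescents
  (an elliptical ventricle would be an unrealistically solid competitor for
  the solidity rule), and an elliptical tumor, bright on T2 (mean 210) and
  homogeneous, placed left, right, or at the midline; optionally an edema
  ring with T2 between tumor and normal tissue — the documented failure
  mode of the automatic cascade, available for stress tests;
* per-class heterogeneity: a multi-scale smooth texture field (box-blurred
  noise at two correlation lengths) scaled by a per-class SD. Normal-tissue
  classes are broad (GM/WM SD 20-24), as in non-normalized in-vivo MR — this
  breadth is what makes 32-cluster over-segmentation give the tumor a group
  of its own. The field is mirror-symmetric about the midline, since
  anatomy and tissue character are roughly bilateral; only the tumor and
  the acquisition noise break left-right symmetry, which is the premise of
  the laterality rule;
* independent Gaussian acquisition noise (SD 5 by default) on every tissue
  pixel; air stays at zero so that zero intensity delimits the head, which
  is what the bounding-box rule's default brain mask assumes;
* the default tumor (semi-axes 31×25 px ≈ 2400 px) sits inside the per-case
  ground-truth range of the published cohort.

What the phantom does **not** emulate: partial-volume mixing at tissue
interfaces, bias fields (the study reports none), gyral/sulcal geometry,
3-D continuity, and pathology other than one tumor plus optional edema.
Passing the phantom checks therefore demonstrates that the implementation
realizes the method's logic under its own assumptions, not clinical-grade
performance on patient data.

## Numerical and design choices

* **Fuzzifier and tolerance.** `m = 2` (the universal FCM default; the
  method's description leaves it open) with `eps = 1e-5` on $|\Delta J|$
  and `max_iter = 300`. On full 256×256 slices $J$ is of order $10^8$, so
  the absolute tolerance effectively lets runs use the full iteration
  budget; both are configurable. The objective is non-increasing by
  construction; tests allow relative slack $10^{-8}$ for floating-point
  plateau jitter. An optional restart scheme (`nstart`) picks the
  lowest-objective of several random starts; it is off by default — on
  phantom panels the lowest-$J$ optimum showed no advantage in tumor
  separation.
* **Initialization** draws memberships uniformly and row-normalizes,
  reproducible through `seed`; ties in defuzzification break to the lowest
  cluster index; empty clusters are retained as empty masks and dropped by
  the candidate stage.
* **Connectivity** defaults to 8 for labeling and growth (the common
  choice for foreground), configurable to 4.
* **Growth candidates** are any image pixels, not only the cluster's own
  mask (`grow_within_cluster` exposes the restricted variant): fragments
  are supposed to grow into the full coherent structure.
* **Linkage.** The 1-D hierarchical splits use *complete* linkage:
  it minimizes within-cluster range, giving the balanced high/low
  separation the rules intend. Average linkage — the other natural
  choice — tends to isolate one extreme value as a singleton cluster and
  discard everything else, including the tumor, an undesirable
  winner-takes-all behavior observed repeatedly on phantom panels. If all
  values are equal no meaningful split exists and all candidates are kept
  (fail-open, favoring recall).
* **Degenerate inputs.** A single-pixel seed has SD 0 and an exact-value
  acceptance interval; identical half-histograms give correlation exactly
  1 (midline); a zero-variance half-histogram that differs from the other
  gives correlation 0; collinear pixel sets have solidity 1; an empty
  ground truth makes PM/CR undefined and is an error, as are zero-variance
  paired differences.
* **Hole filling** is an explicit border flood fill rather than a
  dilation by-product: dilation alone cannot guarantee a hole-free mask.

## Problem sizes

The shipped checks run FCM oracle comparisons on ≤ 32×32 images, growth
and labeling oracles on 16×16 grids, and full-pipeline panels of 20
lateral-tumor phantoms, 20 midline phantoms, and 6 ablation pairs
(generated at noise SD 9 so that the defuzzified groups genuinely
fragment) at 256×256 — sizes chosen so the entire suite completes in a few minutes on a
single core while still exercising every stage end to end.

## Known limitations

* Noticeable edema defeats the automatic cascade (edema is bright on T2,
  like tumor); the underlying study reports the same failure mode, and the
  semi-supervised pathway is the intended workaround.
* The laterality rule presumes well-centered slices; a tilted or shifted
  head would need registration first (out of scope here).
* Single-slice 2-D only; no DICOM series or volumetric processing.
* The pipeline classifies one tumor; multifocal disease would be merged or
  partially discarded by the area rule.
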