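# menseg

Automatic meningioma segmentation from a pair of co-registered,
**non-contrast** T1- and T2-weighted brain MR slices — no contrast agent,
no training data.

Meningioma is a typically benign tumor whose complete surgical resection is
curative, so its margin matters. It is bright on T2-weighted images and,
unusually among brain tumors, often sits at the brain **midline**, where
the symmetry heuristics used by many detection schemes break down. `menseg`
implements a pipeline that handles both lateral and midline tumors:

1. **Joint intensity histogram** — each pixel is a pair
   $x_k = (x_{k,T1}, x_{k,T2})$, tallied in a 256×256 table.
2. **Fuzzy c-means** over the occupied bins (count-weighted, equivalent to
   per-pixel clustering), minimizing
   $J = \sum_k w_k \sum_i u_{ik}^m \lVert x_k - v_i \rVert^2$ with
   $\sum_i u_{ik} = 1$, then defuzzification into `c = 32` binary groups —
   deliberate over-segmentation so the tumor separates into its own group.
3. **Seeded region growing** — each group's largest connected component
   seeds growth; neighbors join while T1 *and* T2 lie within mean ± 2 SD of
   the region statistics, consolidating the fragmented groups.
4. **Knowledge-based selection** — bounding box (≤ half the brain),
   bilateral T2-histogram laterality (Pearson r > 0.95 ⇒ midline, otherwise
   the side with the larger histogram count at the maximal-difference bin),
   solidity (area / convex-hull area) and area, the last two split
   high/low by agglomerative hierarchical clustering; survivors merge by
   logical OR. A semi-supervised mode takes a human candidate choice
   instead.
5. **Morphological refinement** — opening with largest-component retention,
   then hole filling.

Against a ground-truth mask the result is scored with
**PM** = 100·TP/GT (percent match) and **CR** = (TP − 0.5·FP)/GT
(correspondence ratio). A synthetic head-phantom generator with known tumor
masks makes every stage testable without patient data.

## Worked example

```r
library(menseg)

ph  <- generate_phantom(phantom_spec(tumor_position = "left", seed = 11))
fit <- menseg(ph$t1, ph$t2, gt = ph$tumor_mask, config = menseg_config(seed = 11))
summary(fit)
```

```
Synthetic T1/T2 phantom 256x256: 2440 tumor px (left), classes: gray_matter, white_matter, csf, skull, scalp, tumor
menseg segmentation: tumor_found
  32 candidate groups from 32 clusters; laterality left (r = 0.921)
  final mask: 2440 px
  vs ground truth: PM = 100.00%, CR = 1.00

Knowledge-based cascade:
  bounding_box   32 in -> 31 kept
  side           31 in -> 12 kept
  solidity       12 in ->  4 kept
  area            4 in ->  1 kept
  selected cluster id(s): 10
```

Reading: the bilateral-histogram correlation 0.921 is below the 0.95
threshold, so the tumor is lateralized (left) and right-sided candidates
are dropped; the cascade then narrows 32 candidate groups to one, whose
refined mask recovers 100% of the 2440 ground-truth tumor pixels with no
false positives (CR = 1.00). `plot(fit)` shows the slices with the mask
boundary; `fit$kb_trace` holds the per-candidate audit trail.

The published 29-case count table ships with the package:

```r
tab <- recompute_metrics_table(study_counts_path())
s   <- summarize_cases(tab)
# PM 72.76 +/- 36.24 ; CR 0.43 +/- 0.86
```

A thin command-line wrapper lives at `inst/exec/menseg`
(`menseg run --t1 a.png --t2 b.png -o out/`, `menseg phantom`,
`menseg eval`, `menseg table1`).

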