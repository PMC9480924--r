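---
title: "Methods: weighted graph analysis of functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted graph analysis of functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fcgraph` implements a complete group-comparison workflow for resting-state
functional brain networks: per-subject weighted networks are built from
ROI-averaged time series, summarized with five graph measures, compared
between two groups with permutation statistics, and related to behavioral
scores. This vignette documents the model, every tunable that matters, the
numerical conventions, and what the synthetic-data validation does and does
not establish.

## Network construction

Each subject contributes a `T x N` matrix of ROI-averaged signals. Edges are
Pearson correlations between ROI pairs; correlations are kept on the `r`
scale (no Fisher transform is applied to edges). Three processing steps
follow:

1. **Edge-wise confound removal.** For every edge, `weight ~ intercept +
   age + sex` is fit by OLS across all subjects with groups pooled, and the
   weight is replaced by its residual plus the edge's grand mean. Pooling
   groups keeps a group difference from being absorbed into the covariate
   fit of either group alone; restoring the grand mean keeps the weights on
   their original scale. Residualizing on the edge level (rather than the
   time-series level) matches what the per-subject correlation matrices
   represent, and the operation is idempotent to rounding error.
2. **Rectification.** Negative residualized edges are set to zero: the
   downstream measures are defined for non-negative weights, and negative
   resting-state correlations are difficult to interpret without global
   signal regression (which this workflow deliberately avoids).
3. **Proportional thresholding.** The `k = round(s * N(N-1)/2)` strongest
   edges are retained *with their weights* at sparsity `s`. Surviving edge
   sets are nested across sparsities, and ties at the cutoff are broken by
   lexicographic node order; real-valued correlations make ties a
   measure-zero event, so the rule exists purely for reproducibility.

The order residualize-then-rectify is the default (rectifying first would
censor edge values before the covariate fit sees them); the opposite order is
available as a configuration switch, with a second rectification pass
afterwards so thresholding always sees non-negative weights.

**Sparsity selection.** For one subject, the connectedness threshold is the
smallest sparsity at which the largest connected component spans all `N`
nodes, found by binary search over the retained-edge count (valid because the
largest component can only grow as edges are added). The group-level
`selected_s` is the maximum of the per-subject minima — the cheapest network
density at which *every* subject is fully connected — while `min_s`, the
minimum, marks where the first subject connects. Both are additionally
reported rounded to 0.1%. Range analyses use a grid from 8% to 26% in steps
of 1% (19 levels), summarizing each metric by its trapezoidal area under the
curve (AUC) to remove the dependence on any single threshold.

## Graph measures

All measures operate on the weighted (not binarized) thresholded network.
Shortest paths use the standard inverse mapping `L = 1/w`, so a stronger
connection is a shorter path; unreachable pairs have infinite distance. The
Dijkstra/Brandes cores are compiled (C++) with a relative tie tolerance of
1e-12 for equal-length path counting.

- **Strength**: `sum_j w_ij`.
- **Betweenness centrality**: Brandes accumulation with fractional counting
  over equal-length shortest paths, over ordered pairs, normalized by
  `(N-1)(N-2)` (raw values kept as an attribute). The normalized form is the
  one consistent with group-mean nodal values of order 0.01 on ~100-node
  networks.
- **Clustering coefficient**: Onnela triangle intensity
  `cc_i = sum_jh (w'_ij w'_ih w'_jh)^(1/3) / (k_i(k_i-1))` on max-scaled
  weights `w' = w/max(w)`; zero for degree < 2. Bounded in [0, 1] and
  invariant to uniform rescaling.
- **Global efficiency**: mean inverse shortest-path length over ordered
  pairs; unreachable pairs contribute zero (required at low sparsities,
  where networks fragment).
- **Local efficiency**: global efficiency of the subgraph induced on a
  node's neighbors with the node removed and paths confined to the
  subgraph — the neighborhood fault-tolerance reading of the measure. A
  cube-root weighted alternative (stem weights combined with inverse
  neighbor-subgraph distances) is available behind `eloc_variant =
  "cuberoot"`; the subgraph form is the default because it follows the
  verbal definition of the measure directly. On unit-weight graphs all
  measures reduce to their textbook binary values, which the test suite
  checks on canonical graphs alongside brute-force oracle equivalence on
  random graphs.

## Group statistics

Nodal measures are compared with a label-permutation test: subjects are
pooled and reassigned to pseudo-groups of the original sizes, a
pooled-variance two-sample t (case minus control) is recomputed per shuffle
(10,000 by default), and the observed t is declared significant when it
falls above the 97.5th or below the 2.5th nearest-rank percentile of the
node's null. Nearest-rank percentiles are exact and unambiguous at
`n_perm = 10000`. Per-node nulls use independent substreams derived from one
master seed, so a report regenerates bit-identically without inter-node
correlation of nulls. No multiplicity correction is applied to nodal maps by
default — the maps are exploratory, and the per-node empirical p
`(1 + #exceedances)/(n_perm + 1)` is reported so users can apply their own —
with an optional BH column behind a switch.

Global efficiency is compared per subject with a strictly one-tailed rule:
significance requires the observed t below the 5th nearest-rank percentile,
so a case group with *higher* efficiency can never reject. The remaining
node-averaged measures use a one-sided Wilcoxon rank-sum test (exact when
the combined sample size is at most 12, normal approximation with tie and
continuity correction otherwise); a one-sided pooled t-test is available as
an alternative switch because both conventions appear in this literature.
AUC-mode comparisons run the identical machinery on per-subject AUC values.

## Brain–behavior analysis

Within each group, each nodal measure is correlated (Pearson) with each of
16 cognitive subtest t-scores; BH-FDR correction is applied *across the 16
scores* within one (node, metric, group) family — not across nodes, matching
the uncorrected nodal maps. Pairs significant after FDR in either group
proceed to a between-group comparison of correlations: the Fisher-z
difference

```
z_diff = (atanh(r_case) - atanh(r_control)) / sqrt(1/(n_case-3) + 1/(n_control-3))
```

is referred to a label-permutation null (pseudo-groups of the original
sizes, correlations and z-difference recomputed per shuffle), with the
two-sided empirical p `(1 + #[|z_null| >= |z_obs|])/(n_perm + 1)` — the
`+1` estimator avoids reporting p = 0. Degenerate shuffles with |r|
numerically 1 are redrawn and counted. The analytic two-sided normal p is
reported alongside. A sensitivity rerun screens both variables with the
median absolute deviation: points farther than 2.5 scaled-MAD units
(`1.4826 * MAD`, the normal-consistent scaling) from the median are dropped,
a conservative robust-screening multiplier; a zero MAD keeps all points with
a warning. Subjects missing a score are dropped from that score's analyses
before any permutation.

## Synthetic cohort generator

The generator exists so every downstream decision rule can be validated with
known ground truth. Its defaults mirror the design the package targets: 112
nodes in 6 contiguous modules, 29 subjects per group, and 180 timepoints per
subject. Time samples are i.i.d. multivariate normal draws from a block
covariance (unit diagonal, 0.4 within modules, 0.1 between) — no temporal
autocorrelation is simulated, because every downstream quantity depends on
the data only through Pearson correlations, whose sampling noise at T = 180
is realistic for a six-minute acquisition. Group effects attenuate the
covariance rows/columns of chosen effect nodes in the case group by a
multiplicative factor (eigenvalue clipping with diagonal renormalization
repairs the rare loss of positive semidefiniteness, and the repair is
reported). Age/sex confounds mix a shared latent signal into all nodes with
per-subject amplitude `0.2 * (age-20)/50 + 0.1 * [male]` by default — a
rank-one edge confound of the kind edge residualization is meant to remove.
Behavioral coupling adds `slope * standardized(metric)` to one score in the
case group (noise SD 10 on the t-score scale), with
`coupling_slope_for_r()` inverting `r = slope/sqrt(slope^2 + sd^2)` so a
target population correlation (e.g. 0.74) can be planted; the uncoupled
group receives variance-matched noise.

What passing these simulations does **not** show about real data: the
generator has no hemodynamics, motion, scanner drift, spatial smoothing
leakage, or lesion pathology, and its modules are idealized. Calibration and
recovery results therefore validate the *statistical machinery* (type-I
control, direction labeling, power at planted effect sizes), not the
physiological interpretation of any specific regional finding.

## Numerical choices and problem sizes

- Shortest-path tie tolerance 1e-12 (relative); oracle comparisons at 1e-9.
- Edgeless graphs have a largest component of size 1 by convention.
- Zero pooled variance yields t = 0 with a warning rather than an error, so
  degenerate nodes cannot crash a 112-node scan.
- Validation suites use 200 null-cohort replicates at full design scale
  (29 vs 29, 112 nodes) with permutation counts reduced to 1,000, and 40
  replicates for effect-recovery power — sizes chosen to give Monte-Carlo
  standard errors comfortably inside the +/-2% calibration bands being
  asserted.
- The packaged 112-region node table is an AAL-derived reconstruction (90
  cerebral regions, 18 cerebellar lobules, 4 vermis regions) with the
  six-lobe labeling used for report tables; it supplies realistic region
  names, not authoritative atlas coordinates.

## Known limitations

Proportional thresholding can misbehave when groups differ in overall
connectivity strength (the retained edge sets then differ systematically);
the workflow reports mean connectivity so users can check. Only undirected,
non-negative networks are supported — negative-weight and directed variants
are out of scope, as are modularity-based measures. The edge residualization
is linear in age and sex; nonlinear confounds would leak through. Finally,
nodal maps are intentionally uncorrected for multiplicity and should be read
as exploratory.
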