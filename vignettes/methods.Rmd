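---
title: "Methods: probabilistic cell–cell communication networks and differential edge calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic cell–cell communication networks and differential edge calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccnet)
```

## Overview

`ccnet` turns a bulk expression cohort plus cell-type deconvolution scores
into one weighted cell–cell communication network per sample, then calls
edges whose weights separate two clinical groups. This vignette records
the model, its assumptions, the tunable parameters, the numerical
conventions, and the choices we made where more than one defensible design
existed.

## Scaffold construction

The scaffold is the static universe of candidate edges
(producing cell, ligand, receptor, receiving cell). Its only evidence is
cell-sorted reference expression: for each (cell type, gene) and each
reference dataset that contains both, the dataset casts one vote when the
cell type's expression of the gene exceeds the dataset's median expression
level; the gene is accepted for the cell type on a strict majority of
votes.

Three details are under-determined by that description, and are exposed as
options with the following defaults:

* **Replicate aggregation.** A dataset usually carries several replicates
  of a cell type. We collapse them by their median before the comparison,
  so each dataset casts exactly one robust vote
  (`vote_expressed()`), rather than letting replicate counts weight the
  vote.
* **The median compared against.** By default the threshold is the global
  median over every (gene, replicate) value of the dataset — the natural
  reading of "an expression threshold close to the median" in
  TPM-like units. `median_mode = "per-gene"` compares against the gene's
  own median across replicates instead, which asks "is this cell among
  the high expressers of this gene" rather than "is this gene expressed
  at all".
* **Ties.** With an even number of voting datasets, exactly half the
  votes is *not* a majority (`votes > possible / 2`). A gene absent from
  every dataset is reported as "no evidence" (0 possible votes), which is
  distinct from losing 0 of n.

Edges are enumerated over all ordered cell-type pairs, autocrine
self-loops included by default (`include_self_loops = FALSE` drops them).
Edge ids are assigned by lexicographic order of
(lcell, ligand, receptor, rcell), so the scaffold is a pure function of
the *sets* in its inputs, never of row order.

## The edge-weight model

For sample $k$ and edge $e_i = (c_l, l_a, r_b, c_r)$:

$$P(e_i) = P(l_a \mid c_l)\,P(c_l)\; \cdot\; P(r_b \mid c_r)\,P(c_r)$$

* $P(c_l)$ is the empirical CDF of the producing cell's score over the
  whole cohort, evaluated at the sample's score.
* $P(l_a \mid c_l)$ conditions on cell abundance: the cohort is split into
  quartiles of the cell's score distribution, an expression ECDF is fitted
  within each quartile bin, and the sample is evaluated in the bin *its
  own score* selects.

The model assumes that (a) deconvolution scores are monotone in true cell
abundance, and (b) a transcript's abundance, at a given level of the
producing cell, is informative about the channel's activity. It does not
model secretion, diffusion, or receptor occupancy; the weight is a
probability of *possibility*, not a flux.

Numerical conventions:

* **ECDF inequality.** The default is $F(v) = \#\{x \le v\}/n$ (the
  standard R `ecdf` convention). A strict mode (`ecdf_mode = "lt"`) is
  provided; the two differ only at observed support points, which matters
  at small $n$. With the default, the cohort maximum maps to exactly 1 and
  anything below the minimum to exactly 0.
* **Quartile boundaries** use the type-7 (linear interpolation) sample
  quantile, the R default. A score exactly on a boundary goes to the
  lower bin.
* **Degenerate bins.** If a cell's scores are constant, all boundaries
  coincide and conditioning is undefined; the model collapses that
  (gene, cell) to a single unconditional expression ECDF and warns. A
  non-constant score vector that still leaves a quartile bin empty is an
  error naming the (gene, cell) pair, since a silent empty-bin fallback
  would change the model's meaning.
* **Fitting universe.** The model is fitted once on the full configured
  cohort, never per contrast group — group-specific refitting would build
  the group difference into the reference distributions and bias the
  contrast statistic.

The weight model is a pure function of the cohort (no randomness), and
`weight_cohort()` is guaranteed to equal the per-sample loop of
`edge_weight()` — a property the tests enforce against an independent
counting oracle.

## Contrast statistic and resampling null

For groups $x, y$ the signed statistic is
$s_{xy} = (M_x - M_y)/(\omega_x + \omega_y)$ with $M$ the group median and
$\omega = b \cdot \mathrm{med}\,|w - M|$ the MAD scaled by $b = 1.4826$
(the normal-consistency constant). $S_1 = |s_{xy}|$. The statistic is
invariant to shifting both groups by a constant and to positive rescaling,
so it compares location difference in units of robust spread.

**Zero denominators.** When both MADs are zero (more than half of each
group shares one value — common in near-zero-weight edges) the ratio is
undefined. If the medians also agree, the edge plainly shows no
difference and gets $s_{xy} = 0$. If they disagree, the edge is flagged
`degenerate` and excluded from DWE calling: any finite ranking of an
infinite statistic would be arbitrary, and such edges would otherwise
dominate every list. The same rule is applied inside the null.

**The null.** An ensemble of `n_pools` pools (default 3) is drawn with
replacement from the observed weights (default 100,000 each); each pool
yields `n_iter` (default 1e6) statistics computed on freshly drawn groups
of the *contrast's actual sizes*; the DWE threshold is the empirical
quantile at `quantile_level` of the combined statistics. The default
level is $1 - 10^{-6}$, the top-millionth percentile of the combined
draws; because a phrase like "top 1e-6%" is ambiguous between $1-10^{-6}$
and $1-10^{-8}$, the level is an explicit parameter rather than a buried
constant, and scaled-down runs (e.g. 0.99 with $10^4$ iterations) are
first-class. Draws are with replacement at both stages. Each ensemble
member runs on its own substream derived deterministically from the user
seed, so the result is reproducible and member-order independent. The
inner resampling loop is implemented in C++ (Rcpp) using R's RNG; the
test suite pins it to an R-level reimplementation of the same draw
sequence.

Edges are called DWEs when $S_1$ strictly exceeds the threshold; the
output is sorted by $S_1$ descending with edge-id tie-breaks.

## Clinical binarization

Both phenotypes are computed per tissue. PFI: the threshold is the median
time among *uncensored* samples; all samples (censored included) at or
below it are "short" (group x), the rest "long" (group y). A time exactly
equal to the threshold goes to "short" — on continuous times the choice
is immaterial, and including the boundary in "short" keeps the uncensored
median itself in the group it defines. Stage: substages collapse to their
major stage, I–II are "early" (x), III–IV "late" (y); missing or
unparseable stages (e.g. "Stage X") are excluded rather than imputed.

## Ranking by information gain

DWE weights form a samples × edges matrix classified against the group
labels with gradient-boosted trees (maximum depth 2, early stopping after
2 rounds without improvement). Early stopping needs an evaluation set the
original description does not define; we hold out a stratified 20% split
drawn from the run seed and record it in the output metadata. Reported
accuracy is over all samples — the intent is within-data inference of
feature importance, not generalization — with the held-out split's
accuracy reported alongside so neither denominator is hidden. Gain is the
total split-criterion improvement per feature summed over the ensemble
and normalized to sum 1; it is computed from the booster's tree dump.
Because boosting selects one of several correlated features, duplicated
columns do not inflate the selected-feature count — a property the tests
check directly.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the weight model
assumes, with known ground truth:

* **Cell scores** are Beta-distributed (default Beta(2, 5)): bounded,
  right-skewed, deconvolution-like.
* **Bulk expression** of a scaffold gene is log-normal noise plus a
  linear term in the mean score of the cell types expressing it
  (`coupling`, default 10 — comparable in spread to the log-normal base,
  so quartile conditioning is informative but not deterministic).
* **Reference datasets** are constructed so the majority vote provably
  recovers the planted expression map: expressed (cell, gene) values sit
  ~2 orders of magnitude above the dataset median, non-expressed values
  ~1 below, and a block of intermediate filler genes (belonging to no
  pair) is sized so the global median always lands among the fillers.
* **Planted effects**: background pairs are expressed in
  `cells_per_gene` cell types (25 edges per pair at the defaults), while
  planted pairs are expressed in exactly one producing and one receiving
  cell type, so each contributes exactly one edge and the shift stays
  local. Planted ligands gain `effect_sd` (default 3) cohort standard
  deviations in group x, making the true direction +1.
* **Clinical table**: exponential PFI times with a shorter scale in group
  x, independent censoring at `censoring_rate` (default 0.4), stages
  drawn independently of group.

The reference condition (defaults: 200 samples, 10 cell types, 2,000
edges, 50 planted at +3 SD) is what the acceptance checks exercise. The
generator reproduces the *dependence structure* the model assumes; it does
not attempt TCGA's marginal distributions, inter-gene correlation beyond
shared cell scores, tissue heterogeneity, or tumor-cell content. Passing
tests therefore demonstrate correctness and calibration of the machinery,
not biological validity on real cohorts.

One practical caveat the generator exposed: within a single group split,
a chance imbalance in one cell type's scores moves *every* edge using
that cell in the same direction, so per-edge statistics are correlated
across edges. Calibration statements are therefore made against
independently resampled groups (as the null does), not by treating edges
of one split as independent.

## Problem sizes and runtime

The test suite runs the oracle equivalences at 20 samples × 4–8 edges,
the statistic oracle at 1,000 random group pairs, null calibration with 3
pools × 10,000 iterations against 2,000 resampled contrasts, and planted
recovery at the 200 × 2,000 reference condition — about 40 s in total.
The full-default null (3 × 1e6 iterations, pool 100,000) is sized for
real cohort analyses; the C++ kernel makes it linear in
`n_iter × (n_x + n_y)`.

## Known limitations

* Weights are comparable within a fitted model, not across models fitted
  on different cohorts.
* The quartile conditioning uses four fixed bins; very small cohorts
  (< 8 samples) are rejected rather than fitted coarsely.
* The DWE cutoff is a family-level extreme quantile, not a per-edge
  multiple-testing procedure; neighboring edges sharing a cell type or
  gene are not independent discoveries.
* Scaffold membership is binary; an edge absent from the scaffold can
  never be discovered downstream.
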