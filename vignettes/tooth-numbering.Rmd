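---
title: "Combinatorial FDI tooth numbering: model, penalties and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial FDI tooth numbering: model, penalties and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentalabel)
```

## The problem

An intra-oral scan of one dental arch yields a set of tooth *detections* —
point clusters with a binary tooth/gingiva mask, a bounding box and a
center of mass (COM). Numbering them means constructing a binary
assignment matrix $E \in \{0,1\}^{N\times 32}$ over the FDI codes of the
permanent dentition, with each detection carrying at most one code. The
difficulty is combinatorial: dentitions have missing teeth, detectors miss
teeth and hallucinate extras, and the two-digit FDI numerals are not
geometrically ordered (code 18 is the patient's right upper third molar,
28 the left one, and the numerals *decrease* toward the midline in
quadrants 1 and 4). `dentalabel` therefore works on the *arch index*, the
geometric position 0–15 of a code along its jaw, and treats the raw
numeral ordering only as an optional fidelity mode (`code_order =
"numeral"`).

## The three-stage assignment

**Stage 1 — greedy jaw-consistent assignment.** The objective
$f_1 = f_{11} + \lambda_{12} f_{12} + \lambda_{13} f_{13}$ combines the
number of surplus uses per code ($f_{11}$), the number of assignments on
the wrong side of the axial watershed ($f_{12}$) and the number of
unassigned detections ($f_{13}$). The watershed is the axial component of
the mean COM: in a scan containing both jaws it separates the upper from
the lower teeth. With the default weights $\lambda_{12}=0.1,
\lambda_{13}=0.01$ the three terms are strictly ranked: a duplicate (cost
1) is never worth avoiding a wrong jaw (cost 0.1), which is never worth
avoiding a blank row (cost 0.01). Under this ranking the greedy rule is
simple and locally optimal: walk the detections in increasing COM $x$,
give each the lowest free arch slot of its jaw, and leave it unassigned
only when the jaw's 16 codes are exhausted.

Two conventions matter here. First, the indicator comparisons against the
watershed are strict, so a COM exactly on the watershed counts as upper
(configurable via `upper_is_up` for scans with inverted axes). Second,
single-jaw scans are the norm in practice, and the watershed of a one-jaw
scan runs through the jaw's *own* teeth; generated scenes therefore carry a
`jaw_hint` that replaces the watershed side test. Without a hint the
watershed rule is applied literally.

**Stage 2 — sorting.** Within each jaw the multiset of codes from stage 1
is redistributed so that COM $x$ grows with arch index. The penalty $f_2$
counts ordered pairs whose $x$-order and arch-index order disagree (each
unordered inversion contributes 2, via the symmetric double sum with an
exclusive-or indicator). Sorting detections by $x$ and handing out the
used codes in arch order attains the global minimum over all permutations
— 0 whenever the codes are distinct — which the tests verify against an
exhaustive permutation search. If duplicates exist (possible only with
zeroed weights), they sort adjacently by arch index, a deterministic
tie-break.

**Stage 3 — slot placement.** Sorting fixes the *order* but not the
*position*: with missing teeth the codes must skip the right slots. Stage
3 keeps the per-jaw left-to-right order and enumerates all
order-preserving injections of the $m$ detections into the jaw's 16 slots,
$\binom{16}{m} \le 12870$ placements, scoring each by
$f_3 = \sum_{\text{ordered same-jaw pairs}} (\lVert COM_{n_1}-COM_{n_2}\rVert - D_{c_1c_2})^2$
and keeping the minimum (ties to the lexicographically smallest slot
vector). Exhaustive enumeration is exact and cheap at this size, so no
heuristic search is needed. Two design points were genuinely open and are
resolved as follows:

* *Exponent of the distance gap.* The penalty uses the squared difference
  — the standard choice that is non-negative and smooth; an absolute-value
  mode is available (`exponent = "abs"`). The argmin rarely differs.
* *Jaw coverage.* Both jaws contribute symmetric sums; cross-jaw pairs
  never enter any penalty.

**The distance prior.** $D$ is the 32×32 matrix of mean COM distances in
millimeters. `estimate_distance_prior()` averages, for every code pair,
the per-scan COM distance over all labeled scans containing both codes,
and records the support count per entry. Pairs never co-observed stay
*missing* (`NA`), never zero; by default a missing same-jaw entry needed
by $f_3$ is a configuration error naming the pair, and `on_missing =
"skip"` downgrades it to a warning that skips the pair rather than invent
a distance. Only same-jaw entries are used. The CSV interchange format is
a 33×33 grid with FDI codes as header row and column and empty cells for
missing entries.

**The oracle.** `brute_force_label()` is a verification tool, not part of
the pipeline: a depth-first enumeration over each detection's
(jaw-restricted) 17 choices with exact lexicographic pruning — a branch is
cut only when its partial duplicate count plus $\lambda_{13}$ times its
partial unassigned count already exceeds the best $f_1$, or ties it with a
larger partial inversion count. Both bounds are monotone along a branch,
so no lexicographic optimum can be lost. The guard `max_n = 8` per jaw
reflects the combinatorial growth; the tests run it on scenes of up to
four teeth per jaw and additionally check stage 3 against an independent
placement enumeration on a hundred larger scenes.

## Geometric preprocessing

The steps surrounding a detector are implemented exactly as their
contracts state, because downstream budgets are fixed:

* `downsample_uniform()` draws `min(target, V)` vertices uniformly without
  replacement (default 30,000, the detector-stage budget), class-labeling
  each kept vertex by majority over its incident faces. Uniform *random*
  subsampling was chosen over geometric decimation; nothing downstream
  assumes geometric uniformity, and the seeded draw keeps runs
  reproducible.
* `compute_tooth_bbox()` is the minimum *axis-aligned* box; oriented boxes
  are out of scope since grid pooling and box IoU operate on Cartesian
  axes.
* `expand_box()` scales about the center, default factor 1.2 per axis —
  enough to include cervical margins without letting neighbors dominate.
* `sample_points_in_box()` returns exactly `n` points (default 8192, the
  segmentation-stage budget), switching to sampling with replacement when
  fewer candidates exist so the fixed-size contract always holds.
* `grid_max_pool()` voxelizes a featured cloud over its bounding box with
  cubic cells, componentwise max per occupied cell, 0 in empty cells. The
  cell size has no privileged default — it is a resolution choice the
  caller must make.
* The COM is the unweighted mean of tooth-class points; no area or volume
  weighting.

## Evaluation metrics

`classification_metrics()` evaluates accuracy, precision, recall and
IoU = TP/(TP+FP+FN) from contingency counts, reporting a metric as
missing (`NA`) — never 0 — when its denominator vanishes, so absent codes
cannot drag per-tooth means. Detection matching is an optimal one-to-one
assignment maximizing total box IoU (a Hungarian solver written in-package,
cross-checked against exhaustive enumeration), with pairs under the IoU
threshold (default 0.5) discarded; matching is label-aware by default for
per-tooth tables, with a label-agnostic mode for pure detection quality.
Numbering accuracy is reported per FDI code with one 17×17 confusion
matrix per jaw (16 codes plus an `unassigned` class absorbing unmatched
ground truths, unlabeled matches and cross-jaw predictions).

## What the simulator emulates — and what it does not

The synthetic module stands in for real scans and a trained detector. A
template arch places 16 slots on a parabola in the occlusal plane, equally
spaced in arc length (width 56 mm upper / 52 mm lower, depth 46 mm —
typical adult dimensions), with per-code crown extents from adult averages
so molars are wider than incisors. Teeth are box-shaped point clusters
recentred so the noiseless COM sits exactly on its slot; gingiva points
form a band under the crowns. This is deliberately primitive: the labeling
algorithm consumes only COMs, masks and boxes, so realistic crown
morphology would add nothing the tests could detect.

Detector error modes are controlled per `simulation_config()`: missed
teeth (per-tooth probability), isotropic Gaussian COM jitter (the whole
cluster is translated, so boxes, points and COM stay consistent), mask
flips concentrated on the points farthest from the center (mimicking
cervical-margin errors), and spurious detections midway between slots —
positioned exactly where stage 1 must decide between assigning and
leaving unassigned. When a missing-teeth *count* is requested rather than
explicit codes, third molars are removed with weight 8 and premolars with
weight 3 against 1 elsewhere, reflecting where real dentitions most often
lack teeth. Defaults describe a clean scan (no noise, full dentition);
studies switch on the error modes they examine.

Consequences for interpretation: passing closure tests show the
*assignment algorithm* recovers labels under positional noise, missing
teeth and spurious detections. They do not certify performance on real
scanner meshes — crown shape, scanner artifacts, malocclusion beyond COM
displacement and segmentation errors correlated with geometry are all
outside the simulator.

## Numerical choices and degenerate inputs

* Detections are ordered by COM $x$ with ties broken by $y$, $z$, then id,
  making every stage deterministic and the final label map invariant to
  the order detections arrive in.
* Stage-3 ties (distinct placements with equal $f_3$) resolve to the
  lexicographically smallest slot vector; float comparisons use a
  $10^{-12}$ guard.
* Empty scenes, empty boxes and all-gingiva detections are errors, not
  silent results; more detections than slots leaves the surplus unassigned
  and penalized by $f_{13}$ — a data condition, not a failure.
* A degenerate (zero-volume) box has IoU 1 only with an identical box.
* Undefined metrics propagate as `NA` through per-code means
  (`mean(..., na.rm)` is applied only where documented).

## Problem sizes used in validation

The shipped test suite and the acceptance script size their simulations to
run comfortably on a laptop while keeping the statistics meaningful: 1,000
random assignment matrices against literal penalty transcriptions, 200
permutation-optimality scenes and 100 placement-oracle scenes of up to 6
teeth per jaw, 100 noiseless and 200 jittered ($\sigma = 0.3$ mm) closure
scenes, 500 jittered scenes for prior recovery, and a 50-scan noisy
detector study for the metric suite. Tooth clusters shrink to 5–150 points
where only COMs matter, since COM statistics are independent of the
cluster size once recentred.

One validation check deserves a caveat: recovering the template's pairwise
distances from jittered scenes within three standard errors *entrywise* is
statistically fragile by construction. The mean of $\lVert v + e\rVert$
with $e \sim N(0, 2\sigma^2 I_3)$ exceeds $\lVert v \rVert$ by
$\approx 2\sigma^2/d$ — up to 0.025 mm for adjacent teeth at
$\sigma = 0.3$ mm, about 1.3 standard errors at $n = 500$ — and the
maximum of ~120 standardized deviations sits near 3 even for an unbiased
estimator. The practical summary is the maximum absolute prior error,
reported by the acceptance script, which stays below 0.1 mm.

## Known limitations

* Axis-aligned boxes only; no surface-distance (Hausdorff/ASSD) metrics.
* The 32 permanent-dentition codes only: no primary dentition (5x–8x), no
  supernumerary teeth.
* The prior is estimated same-jaw only; cross-jaw relationships are never
  used.
* Mesh I/O covers PLY (ascii, binary little-endian), OBJ `v`/`f` records
  and STL; texture, color and normals are not carried.
* The watershed heuristic assumes the scan's axial direction is meaningful;
  `upper_is_up` must be set correctly for inverted scans, and single-jaw
  scans should provide `jaw_hint`.
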