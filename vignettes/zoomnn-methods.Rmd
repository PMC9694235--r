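---
title: "Zoom-in neural networks for rs-fMRI ROI classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zoom-in neural networks for rs-fMRI ROI classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoomnn)
```

## Overview

`zoomnn` implements a backpropagation-free deep classifier for resting-state
fMRI region-of-interest (ROI) data, together with the full feature and
evaluation pipeline around it. A subject is an `n_rois × n_timepoints`
matrix of ROI-representative signals (the target setting is the AAL-90 atlas,
90 ROIs × 140 timepoints, with subject classes AD, MCI and NC). This
vignette is the package's own account of the models, the numerical choices,
and what the synthetic tests do and do not establish.

## The NEWFM base learner

NEWFM is a supervised neuro-fuzzy classifier. For each feature $i$ and
class $c \in \{0, 1\}$ it holds $m$ triangular membership functions (MFs)
with centers $c_{ij}$ and weights $w_{ij} \in [0, 1]$; the class activation
of a feature value is the bounded sum of weighted memberships

$$b_{ic}(x) = \min\Big(1, \sum_j w_{ij}\,\mu_{ij}(x)\Big).$$

The instance score is $S_c = \sum_{i \in \text{selected}} b_{ic}(x_i)$, the
class decision $\arg\max_c S_c$ (ties to class 0), and the Takagi–Sugeno
defuzzified output (TSD) the normalized contrast
$T = (S_1 - S_0)/(S_1 + S_0)$ mapped to $[0,1]$, with $T = 1/2$ when both
scores vanish. TSD and classification are consistent by construction:
$T > 1/2$ exactly when class 1 wins.

### Membership geometry

Only the sorted centers and the weights are model state. Supports are
re-derived from the centers by the *midpoint-to-neighbor* rule: each
triangle's feet sit at the midpoints toward the adjacent centers (edge MFs
extend outward by the adjacent half-gap). This keeps
$\text{left} \le \text{center} \le \text{right}$ under any center motion.
The alternative — feet at the neighbouring centers themselves — was
rejected after it proved unstable: when centers spread unevenly, a heavy MF
acquires a very wide asymmetric support and bleeds activation deep into the
opposite class's territory, degrading both accuracy and the area-based
feature selection. The midpoint rule trades that leakage for small coverage
dips between well-separated centers, which are harmless because ties fall
back deterministically.

### Training rule

Training is online, winner-take-all and gradient-free. For every instance,
per feature: the membership-maximal MF of the true class moves its center by
$\alpha (x - c)$ and is rewarded, the membership-maximal MF of the opposing
class is punished. Weight updates are proportional,

$$w \leftarrow w + \delta (1 - w) \quad\text{(reward)}, \qquad
  w \leftarrow w - \delta w \quad\text{(punish)},$$

so a weight equilibrates near $I/(I+D)$ when it receives reward and
punishment at rates $I$ and $D$. On an uninformative feature both classes
therefore converge to matched curves, while class-pure regions saturate
toward 1 and 0 — this is what makes the built-in feature selection work.
Clipped additive updates ($w \pm \delta$ truncated to $[0,1]$) were tried
first and rejected: they polarize the two classes' weights into
complementary territories on pure-noise features, producing large spurious
class separation.

Instances are processed in a deterministic low-discrepancy order
(golden-ratio scatter within each class, then a class-balanced weave). With
multiplicative punishment, a class-sorted input table would otherwise let
one class punish unopposed for dozens of consecutive updates
($0.9^{40} \approx 0.015$) and make the fit depend grossly on row layout.
The reorder is a pure function of the labels, so training stays bit
reproducible.

Training stops after `max_epochs` (default 50) or once training accuracy
has not improved for `patience` (default 3) consecutive epochs; the final
state is kept. All constants — $m = 3$ MFs per feature per class,
$\alpha = 0.1$, $\delta = 0.1$ — are exposed as hyperparameters.

### Feature selection

Features are ranked by the non-overlap area between their class curves,
$\int |b_1(x) - b_0(x)|\,dx$ over the training range, computed by the
trapezoid rule on a 256-point grid; ties break toward the lower index. The
area is intentionally unnormalized: it rewards features whose class curves
disagree over a broad range. A consequence worth knowing is that extremely
narrow discriminative clusters score lower than their separability would
suggest, because their curves occupy little of the range.

## The zoom-in learning unit (ZLU)

A ZLU trains a *standard* NEWFM on all instances, splits the training set by
its predictions into misclassified (MI) and correctly classified (CCI)
instances — always a partition — then trains a *subpattern* NEWFM on the
MIs and a *refined* NEWFM on the CCIs. At test time the standard learner is
never consulted; the unit emits the TSD pair $(t_m, t_c)$ of the subpattern
and refined learners.

Degenerate groups (fewer than `min_count = 4` instances, or single-class)
fall back to a copy of the standard model, so the unit's outputs are total.
Feature selection, when enabled, runs once inside the standard training and
the subset is shared by all three learners (independent re-selection is a
switch), keeping them on a common input space.

The mechanism the unit exists for is testable: because the NEWFM score is
additive across features, it cannot express feature interactions. A small
class-1 subcluster planted at the opposite corner of an XOR-like layout is
systematically misclassified by the standard learner, lands in the MI
group, and is recovered by the subpattern learner — the package's tests
verify exactly this, including that the subpattern TSD separates the
subcluster from the background better than the standard TSD. Single-feature
subclusters are *not* a valid test of the mechanism: the standard NEWFM
resolves them on its own.

## The zoom-in neural network (ZNN)

The input feature vector is split into `layers[1]` contiguous equal blocks,
one per first-layer ZLU. After a layer trains, every ZLU emits its TSD pair
for *all* training instances (not only its own group), the pairs are
concatenated in unit order $(t_{m,1}, t_{c,1}, t_{m,2}, t_{c,2}, \dots)$ and
re-split for the next layer; a final output NEWFM trains on the last TSD
vector. Dimension bookkeeping is enforced before any training: the input
width must be divisible by the first layer's count, and twice each layer's
count by the next layer's count. The whole fit is feedforward — no layer is
revisited, no gradient exists.

For layerwise diagnostics a readout NEWFM is additionally trained on each
intermediate layer's TSD matrix. The readouts take no part in the forward
pass; they exist because per-layer accuracies need a defined scoring rule
for intermediate layers, and an explicit readout makes that rule
reproducible. `layer_accuracies()` reports one accuracy per ZLU layer
(through its readout) plus the output layer (through the network itself).

The default architecture is `c(16, 4)`: 16 first-layer ZLUs consuming 20
features each (the 16-ROI × 20-feature design below) and 4 second-layer
ZLUs. The second-layer count is an assumption exposed in
configuration; only the first layer's count is fixed by the reference
design.

## The rs-fMRI feature pipeline

Per ROI, 42 features in a fixed order (`feature_names()` documents the map):

* **Wavelets (32).** The series is truncated to its first 128 timepoints —
  the largest power of two inside a 140-point acquisition and the only
  truncation for which levels 3–4 yield exactly 16 + 8 + 8 coefficients —
  and analysed with the orthonormal Haar transform
  ($a = (x_1+x_2)/\sqrt2$, $d = (x_1-x_2)/\sqrt2$, recursively). The
  $\sqrt2$ normalization preserves energy (Parseval), which both makes
  band energies comparable and gives the tests a sharp invariant. The d3,
  d4 and a4 coefficients are kept: a slow signal of period ~32 timepoints
  concentrates there.
* **Graph measures (10).** Connectivity is the absolute Pearson correlation
  between ROI series (sign is not informative for edge strength), zero
  diagonal, proportionally thresholded to retain the strongest `density`
  fraction of edges (default 0.20; ties break lexicographically so the mask
  is deterministic). On the masked graph: degree, node strength (weighted),
  diversity coefficient (normalized entropy of a node's strength across
  greedy-modularity modules; weighted), betweenness, k-coreness, subgraph
  centrality $\sum_j v_j(i)^2 e^{\lambda_j}$, unit-norm non-negative
  eigenvector centrality, PageRank (damping 0.85) — and two graph-level
  values replicated into every ROI's vector: degree assortativity (defined
  as 0, flagged, when all degrees are equal) and small-worldness
  $\sigma = (C/C_\text{rand}) / (L/L_\text{rand})$ with the null averaged
  over 20 seeded degree-preserving rewirings (10 swap attempts per edge).
  An infinite $\sigma$ sentinel (a null ensemble without clustering, which
  can occur on very sparse graphs) is recorded as 0 in the feature vector;
  $\sigma$ is strictly positive whenever defined, so the sentinel remains
  distinguishable. $\sigma$ is the one feature that is a seeded Monte-Carlo
  estimate rather than a deterministic graph functional; it is equivariant
  under ROI relabeling only in expectation.

The construction details the connectivity graph depends on (correlation
type, sign handling, threshold rule, module definition) are not fixed by
the protocol this package implements; the choices above are explicit and configurable.

## Experimental protocol

`run_assessment()` reproduces the evaluation design: a seeded hold-out split
with a fixed number of training subjects per class (23 by default; with
cohort sizes 34/89/45 that leaves 11/66/22 test subjects); per-ROI NEWFMs on
the 42 features with selection to 20; ROIs ranked by a seeded stratified
cross-validation *within the training split* (the protocol does not say
which data scored the per-ROI models; using held-out data would leak, so
cross-validated training accuracy is used); the top 16 ROIs' selected
features concatenated into the 320-wide ZNN input; layerwise train/test
accuracies reported in percent. Nothing downstream of the split reads test
data before evaluation, and the tests assert this by corrupting test-subject
features and checking that ranking, region choice and the fitted model are
bit-identical.

The three assessments are one-vs-rest pairings — A-NM (AD vs NC+MCI), N-AM
(NC vs AD+MCI), M-AN (MCI vs AD+NC) — which partition the label space.
`roi_overlap()` intersects per-task ROI selections; on the bundled
reference rankings (`aal90_task_rois()`) the intersection is the canonical
seven-region discriminative set.

## The synthetic cohort generator

`simulate_cohort()` emulates the *shape and statistical structure* of an
ADNI-style rs-fMRI cohort, not its physiology. Per subject and ROI the base signal is a
standardized AR(1) process (coefficient 0.3, configurable) scaled to
`noise_sd`. Class information enters in the two channels the downstream
features can detect:

* a slow sinusoid (period 32 timepoints, subject-random phase) on the
  informative ROIs, amplitude `spectral_effect × spectral_profile[class]` —
  its energy lands in the d3/d4/a4 Haar bands, so with random phase the
  classes differ in band *energy* rather than coefficient means;
* a latent AR(1) factor shared within a designated ROI block, mixed with
  weight $\sqrt{\rho_c}$ where
  $\rho_c = \texttt{connectivity\_effect} \times \text{profile}[c]$ is the
  implied within-block correlation. The factor construction is positive
  semidefinite for any $\rho_c < 1$; $\rho_c \ge 1$ is rejected with an
  error naming the block.

Defaults (34/89/45 subjects, 90 ROIs × 140 timepoints, 10 informative ROIs,
`spectral_effect = 1`, `connectivity_effect = 0.3`, `noise_sd = 1`, class
profiles AD = 1, MCI = 0.5, NC = 0) follow the reference cohort's data shape; the
effect sizes and noise level are stated simulation conditions, chosen so
informative ROIs are detectable but not trivial at the reference sample sizes
— nothing is known about the real data's effect sizes, and the generator
makes no claim about them. A cohort is a deterministic function of its spec:
one RNG stream seeded by `spec$seed`, subjects drawn in a fixed order.

What passing the synthetic suite shows: the pipeline recovers planted
spectral/connectivity structure, ranks informative regions first, stays at
chance on null cohorts, and the ZNN outperforms its own base learner under
the generator's conditions. What it does not show: performance on real
rs-fMRI, whose noise spectra, motion artifacts, scanner effects and
spatial voxel structure the generator deliberately omits.

## Numerical choices and degenerate inputs

* Degenerate feature ranges (constant training column) are widened by a
  machine-epsilon-scaled pad and flagged rather than rejected.
* Classification ties go to class 0; ranking ties to the lower index;
  threshold ties to the lexicographically smaller edge — every tie-break is
  deterministic, so identical inputs give identical outputs everywhere.
* Eigenvector centrality on an edgeless graph is an error (there is no
  principal direction); betweenness on disconnected graphs is computed
  within components.
* Cross-validation folds are reduced automatically when a class is smaller
  than the fold count.
* Model files are JSON with a format-version field, numbers written with 17
  significant digits so a write/read cycle round-trips bit-exactly;
  mismatched versions are rejected, not guessed at.
* Null-calibration checks use balanced one-vs-rest designs: NEWFM carries
  no class-prior correction, so under imbalance a null model drifts toward
  the majority rate rather than 50%.

## Problem sizes in the test suite

The statistical properties are exercised at reduced, stated sizes chosen as
the smallest cohorts at which the planted effects are comfortably
detectable: 10–30 ROIs, 40 subjects per cohort, 20 seeds per Monte-Carlo
claim; the exhaustive graph-oracle check covers every labeled connected
graph on up to 5 nodes plus all 6-node graphs up to isomorphism. The
end-to-end acceptance script runs a 30-ROI, 40-subject A-NM assessment with
an `[8, 4]` architecture.

## Known limitations

* The NEWFM internals are this package's own concrete variant of an
  under-documented scheme; the update rule, stopping rule and support
  geometry are faithful to the architecture's description but not to any
  reference source code.
* Binary tasks only; multi-class assessment is done as one-vs-rest.
* The additive NEWFM score cannot represent feature interactions — that is
  precisely the gap the ZLU subpattern mechanism addresses, but single
  NEWFMs (including per-ROI ranking models) inherit it.
* Small-worldness is a stochastic feature (seeded), and on very sparse
  graphs its null can be degenerate (recorded as 0, see above).
* No volumetric image I/O: the package starts from ROI × time tables;
  registration, atlas warping and voxel extraction are upstream concerns.
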