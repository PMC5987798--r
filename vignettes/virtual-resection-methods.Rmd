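---
title: "Virtual resection of structural connectomes: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual resection of structural connectomes: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netresect)
```

## The problem

Anterior temporal lobe resection is the commonest surgery for refractory
temporal lobe epilepsy; roughly two thirds of patients become seizure free,
and it is poorly understood how the removal of tissue reshapes the brain's
white-matter network, or whether the *shape* of that disruption carries
prognostic information. `netresect` implements a change-in-connectivity
("virtual resection") analysis: the patient's own pre-operative network is
the baseline, the predicted post-operative network is obtained by deleting
every tractography streamline that intersects a resection mask, and the
pre-to-post change in network properties is the object of study — no
thresholding against surrogate or random networks is needed. A two-step
machine-learning stage (sparse logistic feature selection, then a
class-weighted linear SVM under leave-one-out cross-validation) relates the
change features to a binary seizure-freedom outcome.

## The network model

**Nodes** are parcellation regions: an integer label volume plus a sidecar
region table (id, name, hemisphere, homologue pairing). **Edges** are
streamline counts: a streamline connects regions *i* and *j* when its two
endpoints (the first and last polyline points — no endpoint dilation) fall
in voxels labelled *i* and *j*. Streamlines with either endpoint in
background are discarded; same-region pairs are stored on the diagonal as
self-connections and excluded from every measure. Mask membership and
endpoint lookup use the voxel-centre convention: world coordinates are
mapped through the inverse affine and rounded to the nearest voxel, ties
half away from zero, 0-based indices. Out-of-bounds points count as
background/outside.

**Virtual resection.** A streamline is removed iff *any* of its stored
points falls in a mask voxel. Membership is tested at the stored points
only, without rasterising the segments between them: tractography step
sizes (≈0.9 mm here and in typical deterministic pipelines) are below the
voxel edge, so every traversed voxel contains a stored point; the phantom
generator likewise guarantees point spacing below the voxel edge, making
the tests independent of this convention. Because streamlines are only ever
removed, the post-operative count matrix is elementwise no greater than the
pre-operative one, removal is monotone in the mask, and global efficiency
can only decrease — these invariants are tested.

**Weights.** Raw edge weights are streamline counts. For the graph measures
the package defaults to `log10(1 + w)`: the count distribution is heavily
right-skewed, and the +1 offset keeps absent connections at exactly 0 and
single-streamline connections positive, whereas a bare `log10` would erase
them. Whether the original analysis applied its log transform before or
after computing graph measures is ambiguous; `metric_weight_kind`
switches between `"log10_transformed"` (default) and `"streamline_count"`.
Change *ratios* (below) are always computed on raw counts, where they are
guaranteed to lie in [0, 1].

**Hemisphere flip.** For right-sided surgery, rows and columns of
homologous region pairs are swapped (midline regions fixed) so that the
left half of every matrix uniformly denotes the surgical (ipsilateral)
hemisphere. The flip is a permutation similarity — spectra and all
permutation-equivariant measures are unchanged — and an involution.

## Graph measures

All measures follow the weighted-undirected conventions of the standard
brain-connectivity toolbox, with self-connections excluded:

* **strength** — row sums of the weight matrix;
* **shortest paths** — Dijkstra on edge lengths 1/w (an absent edge is
  unreachable, `d = Inf`);
* **betweenness centrality** (node and edge) — Brandes accumulation over
  unordered pairs on the 1/w length graph, tied shortest paths counted
  fractionally, *unnormalised* (changes are reported on the raw scale);
* **clustering** — Onnela geometric-mean triangle intensity on
  max-normalised weights, zero for degree < 2;
* **global efficiency** — mean inverse shortest-path length over ordered
  pairs, 1/Inf = 0;
* **communicability** — row sums of `expm(D^{-1/2} W D^{-1/2})` with
  D = diag(strength); zero-strength rows get a unit normaliser, so an
  isolated node has communicability exactly 1.

Shortest-path and betweenness computations are delegated to igraph (whose
conventions match the above and are verified in the tests against
exhaustive path-enumeration and Floyd–Warshall oracles on all graphs of up
to 7 nodes); clustering and communicability are implemented directly since
igraph's weighted variants (Barrat clustering) differ from the toolbox
conventions used here.

**Change metrics.** Quantities that can only shrink under resection —
region volume, region strength, connection strength — are summarised as
ratios post/pre on the count scale (a strength drop from 10 to 2 gives
0.2), with the convention 0/0 = 1 (an absent connection is unchanged).
Quantities that can move either way — node and edge betweenness,
clustering, communicability — are summarised as differences post − pre.
Communicability is treated as difference-type: under degree
renormalisation it can increase after resection, so a ratio bounded by 1
would be wrong. Global efficiency is reported pre, post, and as a ratio.

## Feature assembly

Per-subject change metrics are flattened into a subjects × features matrix
in three deterministically ordered blocks: connection-strength ratios
(strict upper triangle, row-major), region-strength ratios, region-volume
ratios. Eligibility rules keep the dimensionality meaningful:

* connection columns: pre-operative count nonzero in *every* subject, and
  ratio < 1 in at least one subject;
* region-strength columns: strength ratio < 1 in *every* subject;
* region-volume columns: region intersected by at least one subject's mask.

The strength rule deserves a note. Any reduced connection reduces the
strength of both of its endpoint regions, so a "reduced somewhere" rule
would keep almost every region and a completely unrestricted rule keeps
all of them; restricting to regions reduced in every subject captures the
consistently affected core (in a cohort of anatomically similar
resections, a region reduced in all subjects) and keeps the block a small
fraction of the region count, as in the cohort that motivated this
package (85 strength features from 144 regions).

## The outcome classifier

**Step 1 — elastic-net logistic selection.** The weight vector minimises

$$\sum_i w_i \log\!\big(1 + e^{-y_i(x^\top a_i + c)}\big)
  + \tfrac{\rho}{2}\lVert x\rVert_2^2 + \lambda \lVert x\rVert_1,$$

with sample weights \(w_i = 1\), outcomes \(y_i \in \{+1, -1\}\) and an
unpenalised intercept. The optimiser is accelerated proximal gradient
(FISTA) with backtracking line search, soft-thresholding for the l1 term
and adaptive restart; convergence is declared at a relative objective
change below 1e-8 (cap 1e5 iterations; non-convergence is flagged, not
raised). Iteration starts from \(x = 0\) with the closed-form null
intercept \(\log(W_+/W_-)\), so above the critical penalty
\(\lambda \ge \max_j |\nabla_j|\) the exact all-zero solution is returned
rather than numerically-small weights. Features with \(|x_j| > 10^{-8}\)
form the binary selection mask. Tests verify the fit against dense
two-stage grid minimisation on small problems (objective within 1e-6) and
against glmnet under its reparameterisation
\(\alpha = \lambda/(\lambda+\rho)\), \(\lambda_{\text{glmnet}} =
(\lambda+\rho)/n\).

**Step 2 — class-weighted linear SVM.** A soft-margin linear C-SVC
(through e1071/libsvm) on the selected columns, with per-class
misclassification cost \(n/(2 n_k)\): the uniform-prior reweighting that
stops a 36:17 imbalance from teaching the classifier the empirical
distribution. The base cost is C = 1 (configurable; the original analysis
states no value). Features are standardised on the training fold by
default. This matters: change-ratio features concentrate near 1 with small
spread, and without kernel scaling the margin penalty dominates the weight
vector, the decision collapses onto the intercept, and the class weights
then make every leave-one-out fold predict the held-out subject's own
class — the held-out class is always the training minority — yielding
spurious perfect accuracy even on pure noise. With standardisation a
zero-signal cohort cross-validates at chance, as it must. The exact
equivalence of class weighting with minority duplication holds in the
unscaled regime and is tested there (`scale = FALSE`).

**Evaluation.** Leave-one-out cross-validation: for each subject,
selection and SVM fitting use only the other n − 1 subjects
(`selection_scope = "per_fold"`, the default; `"full_cohort"` performs
selection once on all subjects and is offered only for comparison — it
leaks the held-out label into selection). A fold that selects no feature
falls back to the uniform-prior majority — a tie, broken towards
seizure-free — and is flagged. Confusion counts are aggregated over folds
with seizure-free (+1) as the positive class. The (λ, ρ) grid search
evaluates every point (defaults: λ from 0.01 to 0.96, ρ from 0.01 to 1.96,
both in steps of 0.05) and returns the accuracy-maximising point, ties
broken by fewer mean selected features and then by larger λ — the minimum
feature set that separates most accurately. The selected-feature set
reported for the winning point comes from refitting the elastic net on the
full cohort at that point.

## Cohort statistics

Group comparisons use an uncorrected Pearson χ² on 2×2 tables (the
uncorrected statistic exactly reproduces the published cohort-table values
0.5808 / p = 0.4460 for hippocampal sclerosis and p = 0.3353 for
laterality; with Yates correction it does not), tie-corrected
Kruskal–Wallis for age, and a seeded two-sided permutation test on the
difference of means with the small-sample correction
\(p = (1 + \#\{|T_{\text{perm}}| \ge |T_{\text{obs}}|\})/(N+1)\), which
guarantees \(p \ge 1/(N+1)\). One published cohort statistic (the gender
row, χ² = 0.839) is not reproducible from its printed counts under either
the corrected or uncorrected statistic; the package documents rather than
tunes to this discrepancy.

## Synthetic phantoms

The generators exist to exercise conventions and statistics, not anatomy:

* `make_parcellation()` — two mirrored lattices of cubic regions (default
  4 per hemisphere, 4-voxel edges, 2 mm voxels) with a populated homologue
  table; fully deterministic.
* `make_streamlines()` — for each target edge weight w, w straight
  polylines between jittered voxel centres of the two regions (endpoint
  jitter sd 0.2 mm, point spacing ≤ 0.9 mm, both below the voxel edge so
  endpoint lookup and mask membership are convention-independent). Closed
  loop: rebuilding the connectome from a generated bundle recovers the
  target counts.
* `make_resection_mask()` — a contiguous slab covering a requested
  fraction of each target region, confined to one hemisphere.
* `make_cohort()` — change-ratio feature matrices drawn from Beta
  distributions (support [0, 1] matches ratio semantics), parameterised by
  mean and concentration. A planted subset of connection features differs
  in mean between outcome classes by δ: seizure-free subjects get mean
  `baseline_mean − δ` (greater reduction, the direction seen clinically).
  Defaults — 30 subjects per class, blocks of 170/20/10 features,
  10 informative connections, δ = 0.4, baseline mean 0.9, concentration
  20 (sd ≈ 0.07–0.11) — are the study conditions for the recovery and
  null-calibration checks. Class means outside (0, 1) are rejected as
  infeasible. Null calibration (δ = 0) is evaluated at the operating point
  (λ, ρ) selected on the planted cohort: taking the accuracy-maximising
  grid point of a null cohort is optimistically biased by the selection
  over grid points (the expected maximum of ~40 correlated chance-level
  accuracies sits well above 0.5), so the binomial chance band is applied
  where it is valid — at a fixed point.

What the phantoms do *not* emulate: anatomical geometry, curved fibres,
spatially correlated connection loss (each feature is drawn
independently), partial-volume effects at region boundaries, or the
block-wise correlation between connection, strength and volume changes
that a real resection induces. Passing recovery tests therefore show that
the estimator recovers the statistical structure it assumes — not that
real cohorts carry that structure.

## Problem sizes and numerical choices

The test-suite and acceptance computations use 8-region phantoms with tens
of streamlines per bundle, oracle comparisons on all random graphs of up
to 7 nodes (200 seeded trials), and cohorts of 60 subjects × 200 features
with a reduced 5 × 8 (λ, ρ) grid spanning the default ladders — sizes
chosen so a full run completes in minutes on one core while leaving every
code path exercised at the conventions stated above. Other numerical
choices collected in one place: mask binarisation threshold 0.5 on load;
affine consistency tolerance 1e-6; streamline round-trip tolerance 1e-3 mm
(float32 storage); elastic-net zero threshold 1e-8; FISTA tolerance 1e-8
relative; 0/0 change ratios defined as 1; betweenness ties need no
tie-break because all shortest paths are counted fractionally.

## Known limitations

The streamline-deletion model captures only the *immediate* network
change: plasticity, degeneration and long-term rewiring are out of scope,
as is everything upstream of the inputs (registration, tractography
reconstruction, mask drawing). Deleting a whole streamline for any mask
contact assumes remaining portions of cut tracts subserve no function.
Published cohort-level results that depend on clinical MRI data (the
specific selected connections, the 79.2% cohort accuracy) are not
reproducible from synthetic phantoms and are not claimed; the package's
acceptance checks instead verify the arithmetic that *is* reproducible
from printed counts, plus oracle agreement and planted-structure recovery
at stated effect sizes.
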