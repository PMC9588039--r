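---
title: "Surface-based graph convolutional regression: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based graph convolutional regression: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`surfgcnn` predicts a scalar trait from registered brain surface meshes
with a residual spectral graph convolutional network and maps the vertices
that drive the prediction. This vignette explains the model, the
parameters that matter, the design decisions taken where more than one
reasonable choice existed, and what the synthetic validation does and does
not establish.

## Input representation

Every subject is a set of triangulated surfaces registered vertex-to-vertex
to a shared template: an inner (white) and an outer (pial) cortical surface
per hemisphere plus up to seven subcortical structures per hemisphere
(accumbens, amygdala, caudate, hippocampus, pallidum, putamen, thalamus).
The combined template graph is the disjoint union of the per-structure mesh
graphs — edges are triangulation edges with unit weight (an
inverse-edge-length option exists), and no edge crosses a structure
boundary. Cortical graph nodes are defined once per hemisphere by the
inner-surface triangulation; the outer surface contributes coordinates,
not nodes. The concatenation order (left cortex, right cortex, then the
subcortical structures alphabetically, left before right) is fixed so
vertex indices mean the same thing for every subject.

Node features are raw Cartesian vertex coordinates: 6 per cortical node
(inner then outer x, y, z), 3 per subcortical node, or a 9-dimensional
zero-padded vector when both are used together (subcortical coordinates in
entries 1–3, cortical inner/outer coordinates in entries 4–9, the rest
structurally zero). Coordinates are min–max normalized to [0, 1] per
subject and per coordinate axis, pooled over all vertices active in the
chosen mode; a zero-range axis maps to 0. Normalizing per subject rather
than per cohort keeps every subject's features in range regardless of head
size and makes preparation embarrassingly parallel; the cost is that
absolute scale is discarded, which is consistent with rigid-body (not
affine) registration upstream.

## Spectral convolution

With the symmetric-normalized Laplacian `L = I - D^{-1/2} A D^{-1/2}`
(zero-degree vertices get zero rows, hence eigenvalue 0) and its scaled
form `Lt = 2L/lambda_max - I`, a layer computes
`y = sum_k T_k(Lt) x theta_k + b` with the Chebyshev three-term
recurrence. `lambda_max` is estimated per graph by power iteration
(relative tolerance 1e-6, capped at 2 for normalized Laplacians); a
`"fixed"` option uses the upper bound 2, and edgeless graphs use the
`lambda_max = 2` convention so scaling maps them to `-I`. The default
order `K = 3` makes each layer's output depend on a 2-hop neighborhood.
Filters carry `F_in * F_out * K` coefficients plus one bias per output
channel; the bias is standard in this architecture family and excluded
from the parameter-count bookkeeping of the filter itself. A dense
eigendecomposition path (`spectral_oracle`, refused above 200 vertices)
exists purely as an independent oracle for tests; the production path
never materializes `T_k(Lt)`.

Internally a batch is stored channels-first as a `C x (B*n)` matrix whose
column `(j-1)*B + b` is subject `b`'s channel vector at vertex `j`; the
compiled recurrence then makes one pass over the shared sparse Laplacian
per product with contiguous inner loops, and the backward pass evaluates
`sum_k T_k(Lt) theta_k' dY` with the Clenshaw recurrence (K-1 sparse
products). Gradients of every layer are verified against central finite
differences in the test suite.

## Architecture

`build_model()` assembles: a pre-convolution at full resolution; residual
blocks of two BN → ReLU → convolution subblocks whose identity shortcut is
added *before* pooling (so both paths live at one resolution), with an
order-1 Chebyshev projection on the shortcut when channel counts differ;
stride-2 max pooling after each residual block; a post residual block at
the coarsest level; and flatten → dropout (default rate 0.5) → one fully
connected scalar output. Channel widths are configuration; the default
32-32-64-64-128-128 with four residual blocks is this package's choice,
and the small-study preset (below) uses 8-8-16-16 with two blocks. Batch
normalization uses per-channel statistics over batch and vertices,
momentum 0.9 for the running averages used in evaluation mode.

## Pooling hierarchy

The mesh hierarchy comes from repeated heavy-edge matching
(normalized-cut-flavoured edge scores, seeded visiting order): matched
pairs merge into supernodes, coarse edge weights are summed inter-cluster
weights, and unmatched vertices are paired with inserted "fake" vertices
carrying no edges, so every level has exactly half the padded vertex count
of the one below. A sibling-contiguous reordering makes pooling a stride-2
reduction; fake children are neutral in the max and all-fake pairs yield 0.
The hierarchy is computed once per template and shared by all subjects.
Going back up, `upsample_map()` copies each parent's value to its children
level by level, then applies one pass of inverse-distance 1-ring smoothing
(a row-stochastic convex combination, so the value range can never
expand). With sphere-parameterized structures the inverse Euclidean edge
length is a first-order geodesic weight.

## Training

The loss is `MSE + lambda1 * reg - lambda2 * corr`: `reg` is the squared
l2 norm of the filter and fully-connected weights (biases and batch-norm
parameters excluded), and `corr` is the per-batch Pearson correlation
between predictions and targets, defined as 0 for batches with zero
variance (including singletons). The correlation reward counteracts the
regression-to-the-mean shrinkage that plain MSE training exhibits; its
gradient is scale-normalized, which also makes it the term that first
locks onto a weak signal.

Optimization is Adam (defaults: learning rate 5e-4 decayed by 0.99 every
10 steps, batch 32, at most 100 epochs, `lambda1 = lambda2 = 1e-4`,
augmentation probability 0.5) with early stopping on inner-validation MSE
at patience 5 and restoration of the best-validation weights. A
small-cohort preset (`gcnn_hcp_config`) uses batch 50, `lambda1 = 5e-4`,
80 epochs. Augmentation rotates each subject's whole structure set by
three independent angles within ±20° about its centroid and adds i.i.d.
Gaussian coordinate noise (SD 0.02 mm), on raw coordinates before
normalization.

Raw trait scores are Gaussianized by rank: deterministic mode maps rank
`i` (0-based, stable ties) to the normal quantile at `(i + 0.5)/n`;
`sampled` mode maps ranks to sorted seeded standard-normal draws — the
construction used with cohort data, at the price of seed-dependent
targets, which is why deterministic is the default. Normalization is fit
on the full cohort before splitting (mirroring practice with these
cohorts); a leakage-safe path exists via `score_mode = "given"` with
train-fitted scores.

Nested cross-validation partitions a seeded shuffle into six outer folds
(remainders to the lowest-indexed folds; 8070 subjects give outer test
folds of exactly 1345, 1097 subjects give 183 with a 914-subject outer
training complement). Each outer training set splits into five inner
folds; the five early-stopped models predict the outer test fold as a
prediction average. Averaging predictions rather than weights is a
deliberate interpretation: weight averaging is ill-defined across
batch-norm statistics. Per-fold Pearson R values are compared between
input modes by paired t-tests with Benjamini–Hochberg adjustment.

## Saliency

Grad-CAM acts on the last convolutional layer — the post residual block's
final convolution, the deepest layer before the head. Because the head is
linear, the gradient of the prediction with respect to those activations
is exact and cheap; channel weights are node-averaged gradients over real
(non-fake) vertices and the map is the ReLU of the weighted activation
sum, so only positively contributing features are kept. Ensemble maps
average the member models' maps (consistent with prediction averaging);
fold maps average the test subjects' ensemble maps and are interpolated to
full resolution. Pearson spatial correlation across vertices — optionally
restricted to the cortical or subcortical partition — quantifies
robustness between folds, modes or cohorts, and is affine-invariant, so
display scaling of maps is irrelevant.

## Synthetic validation: what it shows

`generate_template()` builds icosphere stand-ins: depth-3 hemispheres
(642 vertices; inner radius 50 mm, outer 52 mm, shared triangulation) and
14 depth-1 subcortical spheres (42 vertices, radius 10 mm) — resolutions
are configuration because the method is resolution-agnostic.
`generate_cohort()` plants, per subject, a radial Gaussian-profile bump of
amplitude `a ~ N(0, 2 mm)` on a 0.7-rad geodesic cap of the left
hemisphere (applied coherently to inner and outer surfaces), adds a smooth
nuisance field everywhere (10 random spherical harmonics of degree ≤ 4,
radial SD 0.5 mm), and records the score `a + N(0, 0.4)` — noise SD one
fifth of the signal SD, so the attainable score correlation is 0.98.

The cap centre deserves a note: it defaults to the mesh vertex nearest the
diagonal direction `(-1, 1, 1)/sqrt(3)`, maximally distant from all three
coordinate axes. Placed near an axis pole, the cap would contain the
vertex that attains the subject's pooled per-axis coordinate extreme, and
the bump amplitude would then leak into the min–max normalization
*denominator* — turning the nominally local effect into a global shift of
every vertex's normalized coordinates that the network happily reads off
any stable vertex. The diagonal placement keeps the coordinate extremes
untouched by the bump (to beyond two amplitude SDs), so the planted
relationship is genuinely local, as the generator is meant to provide.

The reference study (`synthetic_benchmark()`) runs the full nested 6×5
pipeline on 300 such subjects with the small-study preset:
channels 8-8-16-16, K = 3, no dropout, no augmentation, batch 32, Adam at
1e-3, `lambda2 = 1`, at most 18 epochs with patience 6. Two of those
choices deserve comment. The correlation weight is four orders of
magnitude above the large-cohort default because at this scale the
planted signal occupies a low-variance direction of the feature space:
the MSE gradient along it is proportional to that variance and plateaus
at the cohort mean, while the correlation gradient is scale-normalized
and locks onto the direction within a few epochs — exactly the
anti-shrinkage role the loss term is designed for. The epoch budget and
problem sizes (642-vertex hemispheres, 300 subjects) were chosen so the
whole study, which trains 30 networks, completes in minutes on one CPU;
they are study-design choices, fixed before evaluation and not tuned to
any particular outcome.

Passing this study shows that the implementation — encoding,
normalization, hierarchy, convolution, loss, splits, ensembling — can
recover a known localized morphology–score effect end to end. It does
*not* show that the architecture reaches any particular accuracy on real
imaging cohorts: real cortical geometry, registration error, site and
scanner effects, and trait heterogeneity are all absent from the
generator, and the synthetic effect is a single coherent deformation
rather than distributed morphometric variation.

The saliency half of the study deserves a candid caveat. Grad-CAM builds
its map from node-averaged gradients times the last stage's activations.
With a fully connected head the gradient is the weight vector, so the
node-averaging discards the head's spatial selectivity, and what remains
is the activation pattern itself. On this generator the planted
deformation has mean zero across subjects, so the *cohort-averaged*
activations carry no trace of it: the averaged map is dominated by the
filters' static response to template geometry (smooth coordinate
gradients and the icosphere's twelve degree-5 vertices), which is
init-dependent and sits anywhere on the mesh. Models that predict the
score almost perfectly therefore still produce averaged maps that need
not concentrate on the planted cap — a structural property of the
class-activation construction under these symmetric, zero-mean
conditions, not an implementation defect (the per-layer gradients are
verified against finite differences, and the maps respond exactly as the
equations dictate). On real cohorts the situation differs: mean anatomy
itself covaries with the trait, so the averaged activations are
informative — which is precisely the regime the method was designed for.

## Numerical notes and limitations

- Ties in max pooling go to the first sibling; fake vertices never win.
- Batch-norm statistics include fake (padding) vertices; they are a small,
  constant fraction of each level and identical across subjects, so they
  dilute but never bias per-channel statistics.
- A convolution bias feeding a training-mode batch-norm has exactly zero
  gradient (the normalization absorbs constant shifts); finite-difference
  checks on such parameters compare noise against noise.
- The power-iteration `lambda_max` underestimates by at most its relative
  tolerance; Chebyshev stability only needs the spectrum inside [-1, 1],
  which the cap at 2 guarantees for normalized Laplacians.
- Serialization (`save_gcnn`/`load_gcnn`) restores parameters bit-exactly
  and refuses a hierarchy whose template checksum differs.
- FreeSurfer surfaces store float32 coordinates; round-tripping
  millimetre-scale meshes through that format is exact only to ~1e-5 mm.
  PLY is written as float64 and GIfTI as full-precision ASCII.
- Datasets persist via native R serialization (single `.rds` container
  holding template, hierarchy, features and scores).
- The quantile-normalization-before-splitting default mirrors cohort
  practice but technically leaks rank information across folds; the
  leakage-safe alternative is documented above.
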