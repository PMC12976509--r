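---
title: "Scoring mitochondrial morphology from fluorescence fields: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring mitochondrial morphology from fluorescence fields: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mitoscore)
```

## The problem

Mitochondria remodel continuously between fission (fragmentation into
puncta and rings) and fusion (merging into long, interconnected
filaments). The balance between the two is a sensitive readout of cellular
stress and has been linked to neurodegeneration. `mitoscore` quantifies
this balance from single-channel live-cell fluorescence fields: each field
receives a probability vector over three canonical morphology states —
hyperfission (CCCP-like, after the uncoupler commonly used to induce it),
normal (NC), and hyperfusion (FL3-like, after the flavagline that induces
elongation). Field scores can then be aggregated per acquisition batch,
per treatment dose, or per study participant.

Two quantification routes are implemented side by side:

* a **classical morphometry baseline** — per-organelle form factor and
  aspect ratio plus skeleton-graph network statistics; and
* the **patch-based CNN route** — foreground-constrained patch tiling, a
  compact residual convolutional classifier, and Monte-Carlo multi-patch
  ensemble inference.

The classical baseline separates hyperfission from normal morphology well
but is much weaker on the hyperfusion side (the package's own tests assert
this asymmetry on synthetic data); the learned route is the primary
instrument.

## The patch pipeline

Fields are percentile-normalized (1st/99th percentiles to [0, 1]; this
stands in for instrument-specific intensity calibration, which is out of
scope). A foreground mask restricts all analysis to cell-bearing regions.
The default mask comes from a classical segmenter — Gaussian blur
(`sigma = 18` px), Otsu threshold scaled by 0.18, morphological closing
with a disc of the same radius, small-component removal, hole filling —
but any externally produced mask (for example from a learned instance
segmenter) can be supplied wherever a mask argument is accepted. The Otsu
scaling departs from a textbook Otsu cut deliberately: a blurred sparse
cell is a soft-edged blob whose rim intensity falls to roughly half the
interior plateau, so an unscaled threshold erodes the cell boundary. The
factor 0.18 was chosen against simulator ground truth (mean footprint
coverage 0.96, Jaccard 0.72 over 21 default fields) and is a parameter,
not a constant.

Patches of 112 x 112 px are tiled at stride 100 (20 x 20 = 400 placements
on a 2048 px field); a patch is retained when at least 50% of its pixels
are foreground — the boundary case is kept, matching the convention that
patches with *less* than 50% foreground are discarded. Inference draws
`k = 4` patches uniformly without replacement from the filtered pool,
classifies each, and averages; this is repeated for 100 Monte-Carlo rounds
and all round means are averaged into the field score. Because inference
is deterministic per patch, the implementation classifies each pool patch
once and reduces the rounds to a weighted average — numerically identical
to the nested mean, at a fraction of the cost. Per-round sampling seeds
are derived from a root seed, so rounds are order-independent and a single
integer reproduces a whole scoring run. Pools smaller than `k` are sampled
with replacement (with a warning) so sparse fields still score.

## The classifier

No deep-learning framework is assumed: the patch classifier is a compact
residual CNN implemented in the package's own C++ (im2col convolutions,
max pooling, a widening residual stage with a 1 x 1 shortcut, global
average pooling, softmax). The design keeps the ingredients of the
standard residual-network recipe — identity shortcuts, ReLU, Adam,
cross-entropy — at a capacity matched to single-channel microscopy
patches, which carry far less variation than the natural-image corpora
that motivate 18-layer networks. Gradients were verified against central
finite differences (worst relative error below 1e-7).

Training applies the augmentation recipe: random resized crop (area scale
uniform in [0.5, 1], then resize to the network input), horizontal and
vertical flips, 90-degree rotations, and brightness/contrast jitter with
factor 0.8 (multipliers uniform in [0.2, 1.8]). Inference applies none of
it — patches are plainly resized — so all score randomness comes from
patch sampling. Patches are extracted at 112 px and resized to the network
input; the desk profile uses a 96-px input, the paper-scale profile 224.
One addition to the optimizer recipe proved necessary: global
gradient-norm clipping (`clipNorm = 2`). At desk-scale learning rates one
in a few seeds otherwise collapses to a single-class predictor; clipping
removes the failure mode without a scheduler or weight decay (both are
deliberately absent).

Desk-profile defaults: 10 epochs, batch 16, learning rate 3e-3, random
initialization. The paper-scale profile (200 epochs, batch 128, learning
rate 1e-4, 224-px input, ImageNet-style pretraining) is expressible
through the same configuration but is not exercised by the tests; no
pretrained weights ship with the package.

## Classical morphometry

Mitochondria are segmented inside the foreground by adaptive local-mean
thresholding (33-px block, offset 0.05; a global threshold merges dense
networks), objects under 4 px are dropped, and connected components are
labeled with 8-connectivity (implemented in C++; the stock labeler in the
imaging stack is 4-connected, which splits diagonally-touching objects).

Form factor is `P^2 / (4 pi A)`. The perimeter estimator traces the Moore
boundary chain, simplifies it with Douglas-Peucker (1 px tolerance) so
straight edges survive while digitization staircases collapse onto chords,
adds a half-pixel-per-side offset (+2 per closed contour) to recover the
outer-boundary scale, and floors the result at the isoperimetric bound
`2 sqrt(pi A)`, below which no true perimeter can lie. The floor pins
`FF >= 1` for few-pixel puncta, where chord simplification would otherwise
bias FF below its theoretical minimum; measured disc bias is under 5% from
radius 3 px upward, and an 80 x 20 rectangle lands within 3% of its
closed-form FF. Aspect ratio is the major/minor axis ratio of the
moment-equivalent ellipse (pixel-coordinate covariance plus 1/12 per axis
for unit-pixel spread); objects with zero raw minor-axis spread
(effectively one pixel wide) are flagged unreliable and excluded from
summaries.

Network structure comes from Zhang-Suen thinning. Skeleton pixels with one
8-neighbor are endpoints, those with three or more are junction pixels
(adjacent junction pixels merge into one junction), and maximal node-free
paths are branches with geodesic length (1 per axial step, sqrt(2) per
diagonal). Diagonal adjacencies are dropped when the two pixels share an
axial skeleton neighbor, which removes the spurious triangles
skeletonization leaves at corners. Isolated cycles — rings thin to closed
loops — count as one branch with no junction.

## The synthetic study system

No imaging data ships with the package; the study conditions are defined
by a stochastic-geometry simulator with known ground truth. A continuum
coordinate `phi` in [0, 1] controls the morphology mix: per cell, the
generator draws Poisson(`80 (1 - phi)`) puncta (discs of radius 1.2-2.2
px, 30% rendered as annuli — the ring-shaped mitochondria typical of
strong uncoupling) and Poisson(`8 phi`) filaments (smoothed random walks,
heading diffusion 0.10 rad/step, mean arc length `80 (0.2 + 0.8 phi)` px,
width 1.2 px). Above `phi = 2/3` filaments begin to share endpoints with
probability `0.5 (3 phi - 2)`, so hyperfused cells contain a few large
interconnected sub-networks rather than one space-filling mesh. Cells are
non-overlapping discs (radius 70 px, four per 512-px field by default);
all primitives stay far enough inside the footprint that the blurred
signal does too. Rendering is anti-aliased, convolved with a Gaussian PSF
(sigma 1.2 px), scaled to a 30000 peak on the 16-bit scale, and corrupted
with Poisson shot noise plus Gaussian read noise (`noiseLevel = 0.05`).
Class labels partition the continuum at thirds; the boundary is arbitrary
but fixed so tests are stable.

Several geometry constants were calibrated while designing the simulator,
against two requirements stated up front: the foreground segmenter must
recover the cell footprint (coverage at least 0.95 on average), and
classical morphometry on noiseless renders must order the continuum
monotonically (object count down; form factor, aspect ratio, and mean
branch length up). Denser or fatter primitives break the second
requirement — overlapping puncta merge into elongated clusters and
crossing filaments into round meshes, inverting the aspect-ratio trend —
which is why the defaults sit at a sparser density (signal occupies
roughly 5-15% of the cell footprint) than the first-draft values.

What the simulator does *not* emulate: real cytoplasmic autofluorescence
and background gradients, nuclei and multichannel structure, z-dimension
effects (fields are single planes; projection of real stacks is supported
but not simulated), cell-to-cell morphology heterogeneity beyond Poisson
counts, and instrument denoising artifacts. Passing tests therefore show
that the pipeline recovers known morphology differences under controlled
optics and noise — not that it matches any particular instrument's images.

## Evaluation design

Cross-validation is grouped: acquisition batches (`experiment_id`), not
fields, are shuffled and assigned greedily to the lightest fold, so
correlated fields never straddle train and test; the per-fold, per-class
train/test counts are reported in the same layout as the published fold
tables, and fold-score tables append an `Average` row (unweighted mean,
4-decimal report rounding, full precision retained in an attribute).
Binary tasks take the treatment class as positive; the three-class task
reports macro precision/recall and support-weighted F1 by default.

ROC curves sweep the unique scores with tied scores advancing TPR and FPR
together, which makes the trapezoid AUC equal to the Mann-Whitney pair
statistic with ties counted one half; the suite asserts this equivalence
against brute-force pair counting, and against an independent ROC
implementation. Group comparisons use the two-sided Mann-Whitney U test —
enumerated exactly over all assignments when both groups have at most 8
observations (ties counted one half; the stock implementation declines
exact p-values under ties), normal approximation with tie and continuity
corrections otherwise — with Holm adjustment across pairwise comparisons
and rank-biserial effect sizes. Cohort-level prediction reports the ROC of
a chosen participant-mean score (hyperfusion, hyperfission, or an
in-sample logistic combination of both, flagged as in-sample).
Participant aggregation is the unweighted mean over the participant's
fields; weighting by patch-pool size was considered and rejected for
simplicity.

## Problem sizes and numerical choices

The tests and the acceptance script run the desk profile: 90 synthetic
fields of 512 x 512 px (30 per class, six synthetic acquisition batches
assigned round-robin), one grouped fold held out, 10 training epochs,
96-px network input, 100-round 4-patch scoring. These sizes are the
package's chosen desk-scale study conditions; the full-scale profile is a
configuration away but proportionally slower. Determinism contracts: a
fixed `MorphologySpec` seed yields byte-identical fields; a fixed training
seed reproduces final weights on single-threaded CPU execution; scoring is
reproducible from its root seed. Degenerate inputs are defined, not
errors, where a value exists (constant images normalize to zero, empty
masks segment to empty labelings, empty skeletons yield empty graphs);
empty patch pools are a per-field error carrying the field id, and callers
skip such fields with a logged count.

## Known limitations

* The classifier is a compact residual network, not an 18-layer one, and
  no transfer learning is available offline; absolute performance on real
  images is untested by construction.
* The interpretation that the four sampled patches are classified
  independently and averaged (rather than fused into one multi-patch
  input) is one reading of the inference recipe; it is the one
  implemented.
* Published real-data figures (cross-validation metrics on HeLa fields,
  cohort AUCs) are not reproducible here because the underlying images
  are not public; the acceptance layer instead reproduces the printed
  table arithmetic exactly and the qualitative surfaces on synthetic
  data.
* The exact Mann-Whitney branch enumerates all C(n1+n2, n1) assignments
  and is only used when both groups are small (<= 8), as intended.
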