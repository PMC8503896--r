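---
title: "Active-learning annotation of histologic structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-learning annotation of histologic structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Image-based biomarker studies in digital pathology need precise segmentations
of histologic structures — cell nuclei, tubules, regions of epithelium — and
a single whole-slide image can hold hundreds of thousands of them. Annotating
each instance by hand is intractable; annotating a few and letting a model
propose the rest, with the human only accepting or correcting suggestions,
changes the economics of the task entirely. `histannot` is a headless engine
for that workflow: it trains a compact segmentation network concurrently with
annotation, proposes suggestions, simulates the reviewing annotator, and
accounts for the efficiency gained.

Everything runs on synthetic scenes generated in-package, so the full cycle
is testable on any machine with no external data.

# The annotation cycle

One session consists of repeated rounds on a scene cut into fixed-size
patches (256 px by default):

1. **Pretrain.** The network is first trained as an autoencoder on all
   patches (mean squared reconstruction error through an auxiliary 1x1
   reconstruction head). No labels are involved; the features learned this
   way make the patch embedding informative before any annotation exists and
   measurably accelerate the first supervised round.
2. **Select.** Patches are embedded by the channel-wise global average of
   the deepest encoder activations, projected to 2-D, and a dispersed subset
   is chosen by farthest-point sampling — the automated counterpart of a
   user clicking spread-out points in an embedding plot to diversify the
   training set.
3. **Annotate.** The simulated annotator labels the selected patches fully
   from ground truth, paying a per-structure time cost.
4. **Fine-tune.** The network is fine-tuned on all annotated patches with
   per-pixel cross-entropy. Pixels labeled *unknown* carry zero loss weight
   and therefore contribute no gradient: sparse partial annotation is the
   intended supervision mode, and a training gate refuses to run with fewer
   than 3 annotated patches.
5. **Review.** The model predicts on every remaining patch; the annotator
   accepts a suggestion whose pixel f-score reaches the accept threshold
   (one click) or corrects it, flipping each erroneous pixel to the truth
   with probability equal to the correction fidelity.

The two workflow phases reported for interactive annotation tools — an early
manual phase and a late review-dominated phase — are not hard-coded; they
emerge from the accept-threshold rule as the model improves.

# The network

The segmentation model is a symmetric encoder-decoder with skip connections:
`depth` resolution levels, two 3x3 convolutions (ReLU) per block, 2x2 max
pooling, and a decoder that upsamples (nearest-neighbor followed by a 1x1
projection by default; a learned 2x2 transposed convolution is available),
concatenates the skip, and applies two more 3x3 convolutions. A 1x1 head
produces two class logits per pixel.

The pinned reference configuration is depth 5 with base width 4 (channels
4-8-16-32-64), which yields **113,570 trainable parameters** — small enough
to fine-tune on a laptop CPU in minutes, which is the point: the human in
the loop must never wait long. The width, upsampling and normalization
choices were fixed by a one-time configuration search over base width
{4, 8, 16}, upsampling {transposed, nearest+1x1} and normalization
{none, batch} (counting batch-norm affine parameters where present),
selecting the most compact stable variant. The network is
normalization-free: fine-tuning batches here are a handful of patches, where
batch statistics are too noisy to help, and the compact widths train stably
without them.

Training details, all explicit configuration with the defaults in
parentheses: Adam (learning rate 1e-3 for pretraining, 3e-3 for
fine-tuning — chosen on synthetic scenes as the largest rate that never
diverged; 1e-2 oscillates), minibatch size (2 for fine-tuning), epochs per
round (10). The supervised loss reweights the two classes to equal total
weight, because structures of interest typically cover only a few percent
of the pixels and an unweighted loss spends its early epochs predicting
"all background". Every gradient computation was verified against central
finite differences, and all stochastic choices (initialization, shuffling,
correction sampling) derive from explicit seeds, so sessions are
bit-reproducible.

The implementation is pure R: convolutions are im2col gather operations
feeding BLAS matrix multiplications, with hand-derived backward passes and
cached index vectors per tensor shape. A fine-tuning step on a 256 px patch
costs on the order of one second on one CPU core.

# The synthetic scenes

`generate_scene()` emulates three structure scales on a two-color
(purple-on-pink, configurable) palette:

* **nuclei** — random ellipses, semi-axes 4-12 px, Poisson-distributed
  centers, default 300 per megapixel;
* **tubules** — annuli with lumens, outer semi-axes 20-60 px, lumen fraction
  0.4-0.6, default 12 per megapixel;
* **epithelium** — large irregular regions from a thresholded, bilinearly
  smoothed Gaussian field (roughly a third of the area foreground), default
  8 per megapixel.

Overlaps are resolved by draw order (later instance wins), so the ground
truth is a partition; each instance is then reduced to its largest
4-connected component and instances under 10 px are dropped, after which ids
are renumbered 1..K. Additive Gaussian pixel noise has standard deviation
`0.25 * noise` with `noise = 0.3` by default — enough that raw color
thresholding is imperfect and learning is non-trivial. Densities, sizes and
noise are our constructions: the real tissues these scales mirror have no
published statistical description.

What the scenes deliberately do **not** model: texture inside structures,
stain variation and scanner artifacts, touching-instance ambiguity at
scale, and the long-tailed morphology of real tissue. Passing tests on
these scenes therefore demonstrate that the *machinery* (training,
selection, review, accounting) behaves as specified — not that the network
reaches any particular accuracy on real slides.

# Superpixels

`compute_superpixels()` is a SLIC-style windowed k-means in concatenated
(feature, position) space; the compactness parameter (default 1, with
feature channels standardized to unit variance) weights the spatial term.
In *intensity* mode the features are the RGB channels; in *dl_features*
mode they are the full-resolution activations of the last decoder block —
the representation that directly feeds the classification head — assembled
patch-wise by `dl_feature_map()`. Connectivity is enforced afterwards:
fragments that are not their label's largest component are absorbed into a
neighboring main component, and labels are renumbered consecutively.

Boundary adherence is quantified by `boundary_recall()`: the fraction of
reference boundary pixels within a tolerance (2 px default) of any
superpixel boundary. On synthetic scenes, superpixels computed from the
features of a properly fine-tuned model adhere to true structure boundaries
better than intensity superpixels at equal segment count — the
over-segmentation improves as the model improves, which is the argument for
deriving it from learned features in the first place.

# The patch embedding

No UMAP implementation is available in this R stack, so the 2-D projection
is a compact neighbor embedding implemented in the package: a fuzzy
k-nearest-neighbor graph with local connectivity scaling, PCA
initialization (sign-fixed for reproducibility), and stochastic
attraction along graph edges against repulsion from sampled non-neighbors,
with the low-dimensional similarity curve fitted from `min_dist`. It
preserves what the workflow needs — similar patches land together, cluster
structure survives, layouts are seeded — at the tens-to-hundreds of patches
a session handles. `select_diverse()` then runs greedy farthest-point
sampling, which carries the classical guarantee of achieving at least half
the optimal minimum pairwise distance.

# Efficiency accounting

The session log records every action on a **virtual clock**: manual
annotation costs `seconds_per_structure` (default 2 s) per structure,
accepting a reviewed patch costs one click-equivalent (1.5 s), correcting
costs 1 s per ground-truth structure intersecting the error set, and
training costs a deterministic per-patch-epoch amount that counts toward
total but not human time — the annotator is dismissed while the model
trains. Measured wall time is additionally accumulated on the model object.
A virtual clock keeps the identity `human + training = total` exact and
makes logs and reports bit-reproducible under a fixed seed. The cost
defaults are explicit configuration, not measurements; sensitivity analyses
should vary them.

From the log, the report derives:

* `M_t` — extrapolated fully-manual time: the manually annotated patches
  form the timed subset, scaled linearly to all structures
  (`extrapolate_manual_time()`);
* `QA_t_human`, `QA_t_total` — assisted human and total minutes;
* `theta_t = floor(M_t / QA_t_human)` — the integer speed-up multiplier.
  Floor is pinned as the rounding convention: it is the simple rule
  consistent with reporting a 102x gain for a raw ratio of 102.7, and with
  the other published worked examples (9.1 to 9x, 39.2 to 39x);
* the pixel f-score of the assembled final masks against ground truth,
  with `F1 = 2TP/(2TP+FP+FN)` and the both-empty case defined as 1
  (perfect agreement on absence);
* a structures-per-minute curve over binned human time, conservative by
  construction (rates times bin widths sum to the structures completed).

Structure counting defaults to 8-connectivity with a 10 px minimum
component size; published counts rarely state their conventions, so these
are configurable. The component labeler is a run-length union-find
supporting both 4- and 8-connectivity.

# Numerical and degenerate-input choices

* Binarization uses `>= threshold` (ties to positive), threshold 0.5.
* Tiles and patches use 0-based, row-major, half-open coordinates;
  non-multiple canvases are reflect-padded (mirror without edge
  duplication) with padded pixels flagged, and assembly averages
  overlapping contributions.
* An all-unknown mask is not an annotation: such patches count as
  unannotated for the training gate.
* A reference mask with no boundary has undefined boundary recall: `NA`
  with a warning, never 0.
* `density = 0` produces a valid empty scene; predictions on inputs not
  divisible by `2^(depth-1)` fail with a shape error rather than silently
  padding.
* Instance labels persist losslessly in 8-bit RGB PNGs with the id split
  across two channels (`id = 256*R + G`), since the available PNG writer is
  8-bit.

# Scale of the shipped experiments

The test suite and the acceptance script run at desk scale on one CPU: the
headline session uses a 1024 x 1024 nuclei scene (about 300 structures,
16 patches of 256 px), three annotate-train-review rounds of 4 patches with
10 fine-tuning epochs each, and 2 pretraining epochs; module tests use
256-512 px scenes and depth-3 or depth-4 networks. These sizes are the
package's chosen demonstration scale; the machinery itself is agnostic to
scene and cohort size.

# Known limitations

* The simulated annotator reviews every remaining patch each round; its
  cost model is stylized, and `theta_t` at desk scale (few patches, most of
  them manually annotated) is far below what large cohorts with high
  accept rates would show.
* The network trains from scratch per session; there is no transfer from
  external pretrained weights, no GPU path, and no architecture search
  beyond the pinned grid.
* Pyramidal whole-slide formats are out of scope; the engine works on
  tiles and patches.
* The neighbor embedding is not a reference UMAP; with thousands of
  patches its edge-wise R loops would become the bottleneck.
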