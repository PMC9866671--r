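---
title: "Models and methods behind angioquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind angioquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

angioquant analyses phase-contrast micrographs of the Matrigel
tube-formation assay, the standard short-term in-vitro model of
angiogenesis: endothelial cells seeded on a gel matrix assemble into
capillary-like networks of *tubes* (thin elongated structures) connected
at *nodes* (clusters of cells acting as growth and branch points). The
package covers the full analysis chain: a synthetic-image generator with
exact ground truth, mask and annotation I/O, the training loss and
evaluation metrics for three-class segmentation, pixelwise inter-annotator
agreement, small CPU-trainable encoder-decoder segmenters with block-wise
fine-tuning, paired model comparison, and skeleton-graph quantification of
the segmented networks. This vignette documents the models, the defaults
and the numerical choices; it states no result that the package's tests do
not themselves compute.

## The three-class segmentation problem

Every pixel of a micrograph is labelled background (0), node (1) or tube
(2); the dense label matrix is a `class_mask`, the package's central
currency. Segmentation quality is summarised by per-class
intersection-over-union, $\mathrm{IoU}_c = |T_c \cap P_c| / |T_c \cup
P_c|$, and two averages: IoU3, the mean over the three classes, measuring
how well nodes and tubes are told apart; and IoU2, the mean of
IoU(background) and IoU(cells) with cells = nodes ∪ tubes, measuring how
well the cell/background boundary is found. Metrics are computed per image
and averaged (mean ± SEM) across a test set; the pooled alternative is a
matter of passing pooled masks.

Two edge conventions are worth stating. `iou_class()` scores a class
absent from both masks as 1 (vacuous agreement), so per-image values stay
defined on images lacking a class. `iou_summary()` instead *drops* classes
absent from both masks from its average: an all-background truth against
an all-tube prediction scores IoU3 = 0, as it should — a vacuous 1 for the
untouched node class would reward a maximally wrong prediction with
IoU3 = 1/3.

## Focal loss with frequency-derived class weights

Tubes are rare (about 5% of pixels in pooled annotated data, against
roughly 26% nodes and 69% background), so plain cross-entropy
under-weights exactly the class the assay cares most about. Training uses
the multiclass focal loss: per pixel and class $c$, with $p_t = p_c$ when
the true label is $c$ and $1 - p_c$ otherwise,

$$\mathrm{FL}(p_t) = -\alpha_c\,(1 - p_t)^{\gamma}\,\log p_t,$$

summed over the three class channels and averaged over pixels (averaging,
not summing, keeps the loss scale independent of image size). The class
weights are derived from the pooled class proportions as $\alpha_c = 1 -
N_c/N$ (`derive_alpha()`), and the focusing parameter defaults to
$\gamma = 0.5$. At $\gamma = 0$ the loss reduces exactly to an
$\alpha$-weighted sum of binary cross-entropies, which the tests exploit
as an oracle. Probabilities are clamped to $[\varepsilon, 1-\varepsilon]$
with $\varepsilon = 10^{-7}$ before the logarithm; the value is stated so
results are reproducible.

## The segmentation networks

Three decoder families are implemented over a shared small convolutional
encoder: plain Unet (skip connections at each resolution), Unet++ (nested
skip pathways with intermediate decoder nodes — the best performer of the
three on this kind of imagery), and a DeepLabV3+-style variant (parallel
dilated convolutions over the deepest features plus a low-level skip).
The `"toy"` encoder is three stages of paired 3×3 convolutions
(8/16/32 filters by default, two 2×2 max-poolings, downsampling factor 4,
well under 1M parameters) and is the only encoder that resolves offline;
ImageNet-pretrained classifiers are deliberately *not* bundled, and
requesting one raises an error rather than silently downloading weights.
The whole forward/backward machinery is implemented in the package
(im2col convolutions in C++, a small computation-graph engine in R), so
training runs on a plain CPU in minutes; gradients of every architecture
are verified against finite differences in the test suite.

Training uses Adam (default learning rate 3×10⁻³, batch size 4, random
flips and 90° rotations as augmentation); these optimiser settings are
documented configuration, not claims about any reference experiment, and
all of them land in the run manifest. Validation IoU3 is tracked per
epoch and the best-validation snapshot is returned. Large images are
predicted in 256-px tiles with 25% overlap and averaged logits, so
full-resolution micrographs (2584×1936) fit in memory.

### Block-wise fine-tuning

After decoder-only training (`freeze_encoder()`), the encoder can be
fine-tuned one block at a time. `partition_encoder()` packs the encoder's
layer granules (a layer's weight+bias set is indivisible) greedily in
input-to-output order until each cumulative target
$\mathrm{round}(\text{total}/n \cdot b)$ is reached — near-equal blocks,
exact equality being impossible at layer granularity.
`finetune_sequential()` then unfreezes one block per stage, trains it
under k-fold cross-validation (5 folds by default), and carries the
best-validation-IoU3 fold model into the next stage (ties break toward
the earlier fold). The ablation variant re-initialises each newly
unfrozen block before training. Freezing is implemented as a restriction
of the optimiser update to a named parameter set, so the invariant
"trainable parameters at stage i = block i" holds exactly and is asserted
in the tests.

## Paired model comparison

Per-fold IoU3/IoU2 vectors from a shared fold assignment are compared
with a one-sided Wilcoxon signed-rank test: the null is that the first
model's median is no greater than the second's; a claim is made only when
p < α (default 0.05), otherwise no assumption is recorded. Zero
differences are dropped before ranking (Wilcoxon's original treatment)
and tied absolute differences receive mid-ranks. For up to 25 retained
pairs the null distribution is computed exactly by a shift-algorithm
convolution over doubled mid-ranks (exact even under ties; 25 is the
natural cross-validation design size for this test, satisfying the usual
k > 20 rule); larger k falls back to a normal approximation with
continuity and tie corrections. No multiple-testing correction is applied
across pairwise comparisons by default, matching common practice for this
design; a Holm option exists.

## Inter-annotator agreement

Annotation panels (students and experts) are compared with pixelwise
Cohen's kappa over the three classes,

$$\kappa = \frac{N\sum_c |I_c \cap J_c| - \sum_c |I_c||J_c|}
               {N^2 - \sum_c |I_c||J_c|},$$

which equals the generic multi-category kappa computed from the 3×3 pixel
confusion matrix (asserted to 10⁻¹² in the tests). Masks are compared at
full resolution with no resampling. When chance agreement is exactly 1
(both raters constant with identical marginals) the statistic is
undefined; identical masks return 1 by convention and differing ones
raise an error rather than letting NaN corrupt matrix means. Group
summaries average pairwise kappas over student–student, expert–expert,
student–expert and all pairs, reporting sample standard deviations over
the pair values; pair sets with no members are reported as missing.
Landis–Koch bands name the agreement levels, with values at or below zero
reported as "poor/none".

## Skeleton-graph quantification

A mask is converted into numbers in four steps.

1. **Split** (`split_mask()`): node components are 8-connected components
   of node pixels with at least `min_object_px` pixels; tube pixels are
   kept when their cell-union component contains a retained node or
   itself exceeds the threshold. Smaller specks — single cells and
   debris, which carry no network information — are dropped. The default
   threshold is 50 px at the full 2584×1936 micrograph frame, scaled by
   relative image area.
2. **Thin** (`skeletonize_tubes()`): Guo–Hall two-subiteration thinning
   followed by a sequential minimality pass that removes doubled
   staircase pixels (a pixel with ≥2 neighbours forming a single
   8-connected component is deletable without topological change).
   Guo–Hall was chosen after Zhang–Suen proved pathological on this
   geometry: a 45° tube band whose end is cut perpendicular by a node
   disk suffers runaway front erosion that can consume half the band.
   Inside `quantify_mask()` the node blobs are additionally "plugged"
   into the foreground before thinning and masked out afterwards, so tube
   bands never present a bare cut end at a node contact.
3. **Trace** (`build_graph()`): vertices are junction pixel clusters
   (≥3 skeleton neighbours), free endpoints, and node contacts; all
   contacts of one node component collapse onto a single vertex, so tubes
   meeting at a cell cluster meet at one graph vertex. An endpoint within
   `anchor_px` (default 8) of a node — or whose backward-tangent ray hits
   one within three times that reach — anchors to it, and the edge length
   is extended by the anchoring gap, compensating thinning's end erosion.
   Spurs shorter than `prune_px` (default 5) are removed and degree-2
   junction remnants merged back into single branches, so the invariant
   `average_branch_length * branches == total_branch_length` holds by
   construction.
4. **Measure** (`measure_network()`): branches (edge count), closed
   networks (the cyclomatic number $E - V + C$, i.e. independent cycles),
   nodes, network structures and areas (connected components of the cell
   union and their pixel areas), triple- and quad-branched nodes (node
   components with exactly 3 or 4 incident branches), total/average
   branch length, branch-to-node ratio, tube length (alias of total
   branch length), tube coverage area and node area. With a pixel size in
   µm/px, lengths scale by it and areas by its square, exactly.

Branch length is measured on a 5-point moving-average smoothing of the
traced pixel chain rather than by raw √2-weighted chain steps: the raw
chain-code estimator overestimates oblique digital curves by up to ~8%,
while the smoothed polyline is exact on axis-aligned runs and within a
few percent on oblique ones. "Closed networks" is interpreted as the
cyclomatic number of the pruned graph; the underlying assay literature
uses the term without defining it, and alternative readings (e.g. count
of enclosed background holes) coincide with this one on clean networks.
Node-anchored self-loops shorter than `4 * prune_px` are discarded as
boundary artifacts of thinning, not counted as cycles.

## The synthetic-data generator

Real annotated tube-formation datasets are expensive; the generator
produces micrograph-like images with *exact* ground truth so that every
downstream stage is testable offline. A layout samples node disks (radius
8–13 px, tube half-width 3 px on a default 192–320 px canvas) and
connects them with quadratic-Bezier centre-lines through 0–2 random
control points. Acquisition conditions mirror the four categories seen in
practice: `Good` (even illumination), `Dark` (globally lowered
background level), `Defective` (debris ellipses, defocus blur),
`Different` (early-stage incomplete networks, realised by dangling tubes
in the layout rather than by rendering). Cells render darker than
background; with zero noise, gradient, debris and blur the image is
exactly two-level, which pins down mask/image alignment in tests.
Category mixes are apportioned by largest remainder, so the 114:54:79:28
mix of a 275-image dataset reproduces exactly. The photometric defaults
(background 0.72, cell contrast 0.25, noise σ 0.02, Dark background 0.40)
are calibration knobs of the simulator chosen to look plausible for
phase-contrast imagery — they are not measurements of real data, and
nothing downstream depends on their exact values.

Ground truth is computed from the layout geometry: branch count and the
cyclomatic number from the abstract graph, branch length as centre-line
arc length clipped at node-disk boundaries, node area as the analytic
disk area. The generator enforces separation constraints under which
skeleton recovery is well-posed: node centres at least $r_i + r_j +
4\,\mathrm{hw} + 8$ apart, tubes sharing a node fanning out by at least
$2\arcsin((\mathrm{hw}+1)/r)$ so their bands separate at the disk
boundary, curve entry within 25° of radial (a glancing entry leaves a
long tapered band whose skeleton erodes), and clearances of a few
half-widths between non-incident curves and disks. Layouts violating the
constraints are re-sampled; infeasible requests fail with a placement
error. Under these conditions the tests demand — and obtain — exact
recovery of branch and cycle counts over 50 random layouts, total branch
length within 5%, and node area within 2%.

What the generator does *not* emulate: textured cell interiors, halo
artifacts of phase contrast, partially formed or ambiguous structures,
annotation noise. Passing the recovery tests therefore shows the
measurement chain is correct on well-separated networks, not that the
segmenter or the quantifier meet any particular accuracy on real
micrographs; reproducing published accuracy figures would require the
real annotated dataset and large pretrained encoders, which are outside
the package's offline scope.

## Problem sizes used by the tests and the acceptance script

Unit tests run the networks at 32–64 px and the generator at 64–320 px;
the acceptance script trains the toy Unet++ on 64 synthetic 128×128
images for 14 epochs (a few minutes on one CPU core) and verifies
held-out IoU2 ≥ 0.80 at that scale, quantifies 50 layouts at 320×320,
and computes the exact statistics (split counts, kappa, focal-loss
values, signed-rank p) at their natural sizes. These sizes are the
package's chosen desk-scale study conditions.

## Known limitations

- Named pretrained encoders are interface-only; the toy encoder covers
  all contracts but not ImageNet-scale capacity.
- Tube IoU of the desk-scale toy model is modest; the smoke bar is
  deliberately set at the cell/background boundary (IoU2) plus a weaker
  three-class bar, not at publication-level three-class accuracy.
- The quantifier assumes node precedence at node/tube overlaps and
  excludes enclosed background holes from node area.
- CVAT import covers polygon shapes of the "CVAT for images 1.1" flavour
  only.
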