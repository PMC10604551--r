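---
title: "Circle-based keypoint detection of signet ring cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circle-based keypoint detection of signet ring cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Signet ring cells (SRCs) are carcinoma cells whose cytoplasmic mucin pushes
the nucleus into a crescent against the cell rim, giving the cell a ring-like
appearance in H&E-stained tissue. They are roughly circular, vary in size and
colour, and are easy to miss among normal cells, which makes automated
detection in histology tiles attractive. Because the object of interest is
intrinsically round, this package represents detections as *circular bounding
boxes* ("cbboxes"): a continuous centre $(c_x, c_y)$ and radius $r$ in input
pixels, rather than an axis-aligned rectangle. A circle has one fewer free
parameter than a rectangle, matches the cell contour, and admits an exact
intersection-over-union.

## Target encoding and decoding

The detector is anchor-free, in the CenterNet family. Ground-truth circles
are encoded on an output grid down-sampled by the stride $R$ (default 4):

* **Heatmap.** Each annotation of class $s$ contributes a Gaussian bump
  $\exp\!\big(-\,d^2/(2\sigma^2)\big)$ centred on the integer cell
  $(\lfloor c_x/R \rfloor, \lfloor c_y/R \rfloor)$, where $d$ is the cell
  distance to that centre. Overlapping bumps combine by elementwise maximum
  so the map stays in $[0, 1]$ and every encoded object owns a cell of value
  exactly 1.
* **Offset.** Down-sampling discards the sub-cell fraction of the centre;
  the two-channel offset map stores it
  ($c_x/R - \lfloor c_x/R\rfloor$, likewise for $y$) at the keypoint cell.
* **Radius.** The radius map stores $r/R$ (output-grid units) at the
  keypoint cell, which keeps the three regression heads on comparable
  numeric scales.

Decoding selects cells whose value is $\ge$ all 8-connected neighbours
(plateaus keep every cell; ordering is score-descending with deterministic
`(row, column)` tie-breaks), keeps the `top_h` strongest (default 100) above
`score_threshold` (default 0.3), and inverts the encoding:
centre $((u + \delta_x)R, (v + \delta_y)R)$, radius
$\max(0, \hat r)\,R$. Encode followed by decode reproduces the annotations
exactly (to float precision) whenever distinct annotations occupy distinct
cells; this round trip is the codec's core contract and is enforced by the
test suite on seeded synthetic scenes. Optional greedy NMS (circle IoU
threshold 0.5) removes duplicate peaks; score ties break by
$(c_y, c_x, r)$ so results do not depend on input order.

**Choices the method leaves open.** The Gaussian spread per object is not
pinned down by the formulation; we use the size-adaptive rule
$\sigma = \max(1, (r/R)/3)$ in grid units (a pluggable policy), so larger
cells tolerate proportionally larger centre displacement. When two
annotations collide on one output cell, the later one keeps the cell's
offset/radius and a warning is raised. With one object class in the
synthetic data, the heatmap has a single foreground channel; the "two
categories" of the original image-level task (healthy vs affected) are
realised at evaluation time from detections rather than as a second heatmap
channel.

## Network

The backbone is a modified ResNet-34. The conventional stem (7×7/2
convolution + max pool) is replaced by three stacked 3×3 convolutions at
full resolution followed by a CBAM attention block, so no information is
discarded before attention is applied; a 3×3/2 max pool then precedes four
residual stages of 3/4/6/3 blocks whose width doubles per stage
(64/128/256/512), each stage entering at stride 2. The encoder output is at
stride 32; a decoder of three transposed-convolution stages (4×4 kernels,
stride 2, each with batch normalisation and rectification) restores stride
4. Three heads — each a 3×3 convolution (64 channels), rectifier, and 1×1
convolution — emit the class heatmap (sigmoid), the 2-channel offset and the
radius. Residual blocks compute $Z = M(y) + y$ with a 1×1 projection on
shape change; CBAM applies a channel gate (sigmoid of a shared two-layer
bottleneck over global average- and max-pooled descriptors) followed by a
spatial gate (sigmoid of a 7×7 convolution over the channel-wise mean and
max maps).

Numerical choices: weights use fan-in He initialisation; head final layers
use $\mathcal N(0, 0.01^2)$; the heatmap head's final bias starts at
$-2.19$ so the initial foreground probability is $\sigma(-2.19) \approx
0.1$, which keeps the focal loss from being swamped by background early in
training. Batch normalisation uses biased batch variance, $\epsilon =
10^{-5}$ and momentum 0.1 running statistics.

A `tiny` variant (one block per stage, 16 base channels) exists so the whole
pipeline can be trained and evaluated on a single CPU in minutes; it is an
engineering reduction for desk-scale work, not part of the original design.

Because no deep-learning framework is available to R in this project's
dependency set, the package carries its own small CNN stack: convolution,
transposed convolution and max pooling as im2col/GEMM kernels in C++
(RcppArmadillo), batch normalisation, CBAM and the optimiser in R/C++, with
every backward pass verified against central finite differences in the unit
tests. Training is single-threaded and fully deterministic given the seed.

## Objective

The multi-task loss is
$L = L_h + \lambda_r L_r + \lambda_o L_o$, with $\lambda_r = 0.1$ and
$\lambda_o = 1$.

* $L_h$ is the penalty-reduced pixel-wise focal loss with $\alpha = 2$,
  $\beta = 4$: cells whose target is exactly 1 contribute
  $(1-\hat o)^\alpha \log \hat o$; all others contribute
  $(1-O)^\beta \hat o^\alpha \log(1-\hat o)$, so easy negatives are
  down-weighted by $\hat o^\alpha$ and near-peak negatives by the Gaussian
  factor $(1-O)^\beta$. The sum is negated and divided by the keypoint
  count $K$ (the standard normalisation that makes the loss independent of
  image area; an image with no keypoints normalises its background term
  by 1). Natural logarithms; predictions are clamped to
  $[10^{-7}, 1-10^{-7}]$.
* $L_r$ and $L_o$ are L1 losses evaluated only at keypoint cells; the
  offset loss sums the $x$ and $y$ errors per keypoint before dividing
  by $K$.

All three losses expose analytic (sub)gradients, which the tests compare
with finite differences at $10^{-4}$ tolerance.

## Evaluation

Localisation is scored with exact circle IoU: the lens-shaped intersection
of two disks in closed form (zero when disjoint, the smaller disk when
contained, the two circular segments otherwise) divided by the union.
Detections are matched greedily in score order to the unmatched same-class
ground-truth circle of highest IoU $\ge$ 0.5; the precision–recall curve
over pooled, score-ranked detections gives per-class average precision by
all-point interpolation (area under the precision envelope; an 11-point
variant is available), and mAP is the mean over classes with defined AP.
The mean IoU of matched pairs is reported alongside. A rectangle-IoU
convention (`circle_box_iou`) is provided for comparison with box-based
detectors, but circle IoU is the default everywhere a threshold is applied.

Image-level classification derives from detections: an image is called
positive iff any detection scores $\ge \tau$ (default 0.5); accuracy,
precision, recall and harmonic F1 follow from the resulting confusion
counts, with zero-denominator metrics reported as undefined rather than 0.
This detection-score rule is one defensible realisation of the image-level
task, which the original formulation does not specify mechanically.

## Synthetic data

The generator emulates exactly the properties the detector and its tests
depend on, with exact ground truth: ring cells drawn as pale mucin disks
with a darker rim and a crescent nucleus covering ~45% of the rim
circumference, on a pink low-frequency-textured background, plus
unannotated darker elliptical distractors, additive Gaussian noise
(sd 0.02) and a 0.6 px Gaussian blur. Cells have radii uniform in
[8, 16] px on 128×128 tiles, are placed by rejection sampling with centre
distance at least 1.05× the radius sum (so codec round trips are
unambiguous), and positive tiles carry 1–5 cells. The palette loosely
imitates H&E but is cosmetic; the renderer is deliberately schematic.
Passing tests on this data demonstrate that encoding, optimisation,
decoding and scoring are correct and that the architecture can learn
ring-like objects — they do not demonstrate histological performance, which
depends on stain variation, overlapping and partially visible cells,
annotation noise and whole-slide tiling that the generator does not model.

## Augmentation

Flips and quarter-turn rotations are exact grid bijections applied jointly
to pixels and circle centres (radii are invariant); free-angle rotation uses
bilinear resampling with a reflective border and is excluded from exactness
tests; Gaussian blur leaves annotations untouched; random crops keep the
circles whose centres fall inside the window (radii are not clipped — a
deliberate, simple rule for partially cut cells). Offline materialisation
(`augment_dataset`) mirrors the original expand-then-train protocol; a
multiplier of 77 reproduces a 455 → ~35,000 expansion.

## The desk-scale experiment

`run_experiment()` fixes the study conditions used by the acceptance
checks: 250 synthetic tiles (150 positive, 100 negative) split 200/50,
the tiny backbone, 20 epochs of Adam at learning rate 0.001 with batch
size 8 (about 500 optimisation steps — chosen once so optimisation
converges within the epoch budget on a single CPU) and a standard step
schedule that multiplies the learning rate by 0.1 for the final fifth of
the epochs (settling the offset/radius regression), evaluation at circle
IoU 0.5 and $\tau = 0.5$. For the precision–recall evaluation the detector
is decoded with a low confidence floor (0.05) so the full curve is swept,
as is standard for AP; the codec's 0.3 default is an interactive-use
threshold, and the image-level rule is unaffected because it thresholds at
$\tau = 0.5$ anyway. The full-scale defaults elsewhere in the package
(batch 32, 25 epochs, ResNet-34 widths) follow the published training
configuration. All randomness — scene content, split, weight
initialisation, batch order — derives from one master seed, and repeated
single-threaded runs are byte-identical.

## Known limitations

* Offset and radius are supervised only at ground-truth cells, so their
  predictions at slightly mislocalised peaks are extrapolations; with the
  small step budget this is the dominant localisation error source.
* The decoder and head structure are standard keypoint-detector practice
  but not uniquely determined by the original description; published
  parameter counts are therefore indicative only and not reproduced.
* Batch normalisation couples predictions within a batch during training;
  inference uses running statistics and is batch-independent.
* The CSV/JSON annotation dialects are intentionally minimal (circle
  regions only); rectangle or polygon regions in VIA projects are skipped
  with a warning.
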