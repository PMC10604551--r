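# circlenet

Anchor-free detection of signet ring cells (SRCs) in histology tiles using
**circular bounding boxes**. SRCs — carcinoma cells whose mucin-filled
cytoplasm crushes the nucleus into a crescent at the rim — are roughly round,
so the package parameterises a detection as a centre and radius
$(c_x, c_y, r)$ instead of a rectangle, and scores overlap with the exact
circle IoU.

The package is aimed at readers who want a complete, CPU-testable
implementation of a circle-based keypoint detector: every stage from target
encoding to evaluation is exposed as a documented R function, exercised by a
seeded synthetic tile generator with exact ground truth.

## The method

* **Encoding** (stride $R = 4$): each ground-truth circle becomes a Gaussian
  bump $\exp(-d^2/2\sigma^2)$ on a per-class centre heatmap (bumps combine by
  max; $\sigma = \max(1, (r/R)/3)$ in grid cells), a sub-cell offset pair
  $(c_x/R - \lfloor c_x/R \rfloor,\; c_y/R - \lfloor c_y/R \rfloor)$, and a
  radius $r/R$, the latter two stored at the keypoint cell.
* **Network**: modified ResNet-34 — the 7×7/2 stem is replaced by three 3×3
  convolutions plus a CBAM attention block (channel gate, then spatial gate)
  at full resolution — followed by a transposed-convolution decoder back to
  stride 4 and three heads (heatmap/offset/radius). Implemented on a compact
  im2col + GEMM CNN stack (RcppArmadillo) with finite-difference-verified
  backward passes; training is single-threaded and fully seeded.
* **Objective**: $L = L_h + 0.1\,L_r + 1.0\,L_o$ with the penalty-reduced
  focal heatmap loss ($\alpha = 2$, $\beta = 4$) and L1 offset/radius losses
  at keypoint cells.
* **Decoding**: 8-neighbour local maxima, top-$H$ peaks over a score
  threshold, inverted encoding, optional circle-IoU NMS.
* **Evaluation**: greedy matching at circle IoU ≥ 0.5, all-point-interpolated
  per-class AP and mAP, mean matched IoU, and image-level
  accuracy/precision/recall/F1 (an image is positive iff any detection scores
  ≥ 0.5).

## Worked example

```r
library(circlenet)

# one synthetic tile with exact ground truth
sc <- generate_scene(scene_spec(seed = 5, n_cells = 4))
sc$annotations
#>          cx       cy         r class_id
#> 1 107.16834 42.71318 10.915616        1
#> 2  56.15093 74.94152 10.765414        1
#> 3  80.25356 16.09659 11.810854        1
#> 4 102.52164 84.94818  9.034287        1

# encode -> decode round trip is exact
tm <- encode_targets(sc$annotations, dim(sc$image)[1:2], codec_config())
decode_detections(tm$heatmap, tm$offset, tm$radius, codec_config())
#>          cx       cy         r class_id score
#> 1  80.25356 16.09659 11.810854        1     1
#> 2 107.16834 42.71318 10.915616        1     1
#> 3  56.15093 74.94152 10.765414        1     1
#> 4 102.52164 84.94818  9.034287        1     1

# full pipeline: generate 250 tiles, train the tiny backbone on the 200-tile
# train split (20 epochs, Adam, lr 0.001), detect and evaluate on the 50
# held-out tiles (about 10 minutes on one CPU)
res <- run_experiment("work", seed = 1)
#> epoch   1  loss 2.1751  (heat 1.6968  radius 1.3022  offset 0.3481)
#> ...
#> epoch  20  loss 0.0894  (heat 0.0098  radius 0.1517  offset 0.0644)
#> circle detection evaluation (50 images)
#>   mAP@cIoU0.50: 0.9023   mean matched IoU: 0.7072
#>   accuracy 1.0000  precision 1.0000  recall 1.0000  F1 1.0000
#>   TP 30  FP 0  TN 20  FN 0
```

`mAP@cIoU0.50` is the mean (over classes) area under the interpolated
precision–recall curve with matches requiring circle IoU ≥ 0.5; the
image-level row treats an image as SRC-positive iff any detection scores
≥ 0.5. A command-line interface wrapping the same functions ships in
`inst/cli/circlenet` (subcommands `generate`, `augment`, `train`, `detect`,
`evaluate`, each taking `--config <yaml>` and `--seed`).

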