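# flater

Hybrid convolutional–transformer classification of gastrointestinal
endoscopy images, implemented end to end in R.

Endoscopy triage asks two questions of every frame: *is anything wrong?*
(normal vs diseased) and, if so, *what?* (ulcerative colitis, polyps or
esophagitis). `flater` implements a compact network — FLATer — that answers
both simultaneously from one shared representation:

```
image ──► residual conv stem ──► patchify + CLS + positions
      ──► N pre-norm transformer layers ──► final LN ──► CLS embedding F2
      ──► spatial attention: F = σ(Conv3×3[MaxPoolc(F2′); AvgPoolc(F2′)]) ⊙ F2′
      ──► binary head (2-way)  +  ternary head (3-way)
```

* **Residual stem** (local features): `z1 = ReLU(BN(Conv3×3, stride 2))`,
  `z2 = Upsample(BN(Conv3×3))`, output `ReLU(z2 + BN(Conv1×1(I)))` — same
  resolution and channel count as the input.
* **ViT backbone** (global attention): `f′ = MHSA(LN(f)) + f`,
  `f = FFN(LN(f′)) + f′`; token length `L = (H·W)/P² + 1`, embedding
  dimension `P²·C = 768` at the ViT-B/16 default geometry (configurable
  depth 12/6/4, one encoder layer = 7,087,872 parameters at full width).
* **CLS spatial attention**: the CLS embedding reshaped to a 16×16×3 map,
  channel-pooled (max ‖ mean), convolved and sigmoid-gated.
* **Dual heads** trained jointly:
  `loss = w_bin·CE(binary) + w_ter·CE(ternary | diseased samples)`.

The forward *and* backward passes (convolution, batch/layer norm, bilinear
resampling, multi-head attention, GELU MLP, sigmoid gating), AdamW, and the
training loop are written in R on BLAS-backed matrix operations; the backward
pass is validated against finite differences in the test suite, and fixed
seeds give bitwise-reproducible runs. Evaluation implements exact
confusion-matrix accounting (precision, recall, accuracy, F1, macro
averaging, positive class = diseased), threshold-sweep ROC/AUC, the
progressive dataset-extension protocol, an ablation-study driver over the
four architecture variants (`full`, `no_residual`, `no_spatial_attention`,
`vit_only`) and stem saliency maps. A seeded synthetic endoscopy-image
generator makes every stage testable offline — no downloads, no GPU.

## Worked example

Train a desk-scale model on strongly separable synthetic images and evaluate
both tasks:

```r
library(flater)

spec <- synthetic_spec(preset = "desk")          # small resolutions for CPU work
sizes <- data.frame(class = flater_classes(),
                    train = c(80L, 27L, 27L, 26L),
                    validation = c(20L, 7L, 7L, 6L),
                    test = c(20L, 7L, 7L, 6L))
ds <- synthesize_dataset(spec, sizes, seed = 7)

cfg <- flater_config(image_size = 32, patch_size = 16, embed_dim = 48,
                     stem_mid_channels = 8, num_heads = 4, depth = 2,
                     mlp_ratio = 2)
model <- flater_model(cfg, seed = 1)
#> <flater_model> variant 'full', 76,001 trainable parameters

tc <- train_config(epochs = 12, batch_size = 16, learning_rate = 1e-3,
                   lr_schedule = "constant", seed = 1, augment = FALSE)
res <- fit(model, ds, tc)
tail(res$history[, c("epoch", "loss", "train_binary_acc",
                     "val_binary_acc", "val_ternary_acc")], 3)
#>    epoch      loss train_binary_acc val_binary_acc val_ternary_acc
#> 10    10 1.0104699          0.80625          0.825            0.80
#> 11    11 0.8017678          0.86875          0.550            0.70
#> 12    12 0.7070706          0.93125          0.900            0.85

ev <- evaluate_model(res$model, ds$test, task = "binary")
ev$metrics
#> accuracy 0.8500  precision 0.8182  recall 0.9000  F1 0.8571
ev$confusion
#> <confusion matrix> 40 samples, accuracy 0.8500
#>           predicted
#> truth      normal diseased
#>   normal       16        4
#>   diseased      2       18
ev$roc$auc
#> [1] 0.97
```

The training loss falls from chance to 0.71 in twelve epochs and the binary
head reaches 93 % training / 85 % test accuracy on 40 held-out images —
the generator's class signatures are constructed to be learnable at this
scale (see the methods vignette for what that does and does not demonstrate
about real endoscopy data). `evaluate_model(..., task = "ternary")` scores
the disease classifier on the ground-truth diseased subset the same way, and
`progressive_evaluation()` / `ablation_study()` reproduce the
dataset-extension and component-ablation protocols.

A command-line interface wraps the same functions:

```sh
FLATER_CLI=$(Rscript -e 'cat(system.file("cli", "flater.R", package = "flater"))')
Rscript $FLATER_CLI synth --out data/ --seed 7 --scale 0.05 --preset desk --write-images TRUE
Rscript $FLATER_CLI train --data data/manifest.csv --out run/ --depth 6 --epochs 10
Rscript $FLATER_CLI eval  --checkpoint run/checkpoint.rds --data data/manifest.csv --out run/reports
```

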