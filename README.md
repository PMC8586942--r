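# tinysegnet

Tools for segmenting *tiny* objects — a few pixels across — in photographs
whose background dominates by more than 99:1, the regime of microplastic
particles (3–10 px) photographed on beach sand. The package provides:

* **Five encoder–decoder architectures** as explicit layer graphs: U-net,
  Half U-net, MultiResUNet, Half MultiResUNet and Quarter MultiResUNet —
  the Half/Quarter variants keep only the shallow encoder stages that
  matter for small features.
* **Class-imbalance weighted binary cross-entropy**: per-class weights
  `wT = P/ΣY`, `wF = P/(P−ΣY)` so foreground and background contribute
  equally to the loss.
* **Recall-weighted metrics**: `rw F1 = F1 · recall` and
  `rw mIoU = mIoU · recall`, which penalise missed particles twice —
  recall 1 with precision 0.25 scores rw F1 = 0.40 (the minimal
  practicality bar), while recall 0.4 with precision 0.4 scores 0.16.
* **Complexity accounting**: exact parameter counts, forward-pass FLOPs
  (multiply–accumulate = 2 ops, bias included) and receptive fields for
  any model graph, with per-node breakdowns.
* **Data pipeline**: 512-px tiling with 100-px overlap, geometric
  augmentation (±20% shift, ±45° rotation, flips, mean-fill), a synthetic
  sand-scene generator (granular texture + 3–10 px particle disks,
  foreground < 1%), and 72/8/20 five-fold splits.
* **Training**: Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-7), staircase 4% decay
  every 800 steps from 1e-3, seeded and fully reproducible, implemented on
  single-precision BLAS kernels (Rcpp/Armadillo) — no external deep
  learning framework.
* **Layer-utilization analysis**: per-layer kernel weight histograms and
  zero-concentration statistics that quantify which encoder stages still
  learn features, reproducing the reasoning that derived the Half/Quarter
  architectures.

## Worked example

```r
library(tinysegnet)

# forty seeded synthetic sand scenes, 64 x 64, <1% foreground
scenes <- synth_dataset(40, scene_config(size = 64L), seed = 7)
mean(scenes[[1]]$mask)            # foreground share: 0.0051

# build and inspect the smallest architecture
model <- build_model("quarter_multiresunet", input_shape = c(64L, 64L, 1L))
model
#> <model_spec> quarter_multiresunet
#>   input  64 x 64 x 1
#>   output 64 x 64 x 1
#>   39 nodes (22 conv layers), 43,753 parameters

# train briefly and evaluate on held-out scenes
fit <- tinyseg_fit(model, scenes[1:30],
                   train_config(epochs = 10L, seed = 1L))
pred <- predict(fit, scenes[[31]]$image)              # binary mask
m <- metric_suite(confusion_counts(scenes[[31]]$mask, pred))
m
#> segmentation metrics (pooled pixel counts):
#>    recall precision        f1      miou     rw_f1   rw_miou
#>    1.0000    0.2234    0.3652    0.2234    0.3652    0.2234

# complexity of the full-size model
complexity_report(build_model("quarter_multiresunet", c(512L, 512L, 3L)))
#> complexity of quarter_multiresunet:
#>   parameters     : 44,509 (0.0445 M)
#>   forward FLOPs  : 21.9 B
#>   receptive field: 28 px
#>   (39 nodes; print the underlying data frame for the breakdown)

# which stages did the training actually use?
utilization_report(fit)
```

Ten epochs already reach recall 1.0 with modest precision (rw F1 = 0.37
on the scene above); the 50-epoch property check in
`tests/testthat/test-acceptance.R` reaches pooled rw F1 ≈ 0.6 on 160
held-out 128 px scenes, clearing the 0.4 practicality bar.

A thin command-line front end over the same functions ships in
`inst/cli/tinysegnet` (subcommands `complexity`, `synth`, `eval`, `train`,
`histogram`, `crossval`).

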