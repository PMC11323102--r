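# ccgan

Adversarial semantic segmentation for medical images with severe
foreground/background class imbalance, in pure R.

## The problem

In lesion segmentation the foreground — the tumour, the infarct, the
nodule — typically covers a few percent of the pixels. Models trained
with plain pixel-wise objectives inherit that prior and under-segment:
precision looks fine, sensitivity collapses. This package implements a
conditional contrastive GAN (CCGAN) built around three mechanisms that
push back against the majority class, for researchers who want the whole
method — losses, attention, rebalancing, correction, training loop —
as small, tested, inspectable R code:

* a **conditional GAN**: the generator G maps an image *a* (plus
  dropout noise *n*) to per-pixel class probabilities; the discriminator
  D judges (image, mask) pairs, per the usual minimax
  `min_G max_D  E[log D(a, o_seg)] + E[log(1 − D(a, G(a, n)))]`;
* a **conditional contrastive (2C) loss** coupling the discriminator's
  image projections l(I) to learned class embeddings e(M) at temperature
  t = 3:
  `2C(I_i, M_i; t) = −log [ (e^{⟨l_i,e_{y_i}⟩/t} + Σ_{j≠i, y_j=y_i} e^{⟨l_i,l_j⟩/t}) / (e^{⟨l_i,e_{y_i}⟩/t} + Σ_{j≠i} e^{⟨l_i,l_j⟩/t}) ]`,
  combined with an L1 term into the generator objective
  `m_seg = 2C + λ‖o_seg − G(a,n)‖₁`;
* **class-specific channel attention**: per-class channel groups are
  global-max-pooled to class scores `C_j = (1/x) Σ_k max(Î_{j,k})` and
  averaged to semantic maps; the score-weighted map
  `C_A = (1/L) Σ_j C_j Ĩ_j` reweights the features elementwise;
* a **region rebalancing module (RRM)**, a training-only auxiliary head
  classifying 32×32 regions with a frequency-weighted softmax loss
  `−log( F(y) e^{A_y} / Σ_k F(k) e^{A_k} )`, where F counts regions
  containing each class across the training fold;
* **SCoLN**, a UNet corrector trained to predict the generator's
  false-negative and false-positive maps `C_ln = clamp(g − p, 0, 1)`,
  `C_lp = clamp(p − g, 0, 1)`; the final mask thresholds
  `clamp(p + C_ln − C_lp, 0, 1)`.

Evaluation uses Dice `2TP/(2TP+FP+FN)`, Jaccard `TP/(TP+FP+FN)`,
precision and recall, reported per sample as mean ± sd per fold.

There is no deep-learning framework underneath: the package carries a
compact CPU convolutional core (C++ `im2col`/`col2im` patch extraction,
BLAS matrix products, a reverse-mode tape) sized for desk-scale
experiments, with every loss checked against brute-force scalar oracles
in the test suite.

## Worked example

A synthetic imbalanced-lesion benchmark (speckle-textured background,
1–3 bright elliptical lesions, ~3% foreground) stands in for real
imaging data:

```r
library(ccgan)

dataset <- generate_synthetic(synth_config(100, 64, 0.03, seed = 7))
dataset <- lapply(dataset, preprocess, target_size = 64)
mean(sapply(dataset, function(s) mean(s$mask > 0)))
#> 0.0297   # realized foreground fraction

gcfg <- generator_config(levels = 3, base_filters = 8,
                         attention_levels = c(2, 6), region_size = 32,
                         proj_dim = 32)
tcfg <- train_config(epochs = 12, batch_size = 16, optimizer = "adam",
                     lr = 0.002, folds = 5, early_stop_patience = 4, seed = 1)
fit <- fit_ccgan(dataset, tcfg, gcfg, folds_to_run = 0, verbose = TRUE)
#> fold 0 epoch 1: val dice 0.0808
#> fold 0 epoch 4: val dice 0.2477
#> fold 0 epoch 8: val dice 0.7268
#> fold 0 epoch 12: val dice 0.8644

fit$metrics[, c("fold", "n", "dice_mean", "dice_sd", "precision_mean",
                "recall_mean")]
#>      fold  n dice_mean    dice_sd precision_mean recall_mean
#> 1       0 20 0.8643998 0.03827259      0.8036017   0.9382517
#> 2 overall 20 0.8643998 0.03827259      0.8036017   0.9382517
```

Held-out Dice 0.864 ± 0.038 after 12 epochs on one CPU (~2 minutes);
recall 0.94 against precision 0.80 — the corrected model errs toward
*finding* the lesion, the intended antidote to majority-class bias.
Segment and inspect individual images:

```r
val <- dataset[sapply(dataset, function(s) s$fold) == 0]
res <- predict_ccgan(fit$folds[["0"]]$nets$generator,
                     fit$folds[["0"]]$nets$scoln, val[1:3])
evaluate_samples(res, val[1:3])$dice
#> 0.923 0.854 0.906
overlay(val[[1]]$image, val[[1]]$mask, res[[1]]$mask, "overlay.png")
# green = correct foreground, red = missed (FN), blue = spurious (FP)
```

Real data enters through `load_dataset()` (PNG/TIFF `<stem>.png` +
`<stem>_mask.png` pairs, or NIfTI image+mask volumes sliced to 2-D) and
the same `preprocess()` chain (bilinear resize, optional CLAHE, per-channel
Z-score). A thin command-line front end ships in `inst/cli/ccgan`
(`synth`, `train`, `predict`, `evaluate` subcommands with a YAML config
mirroring `train_config()`).

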