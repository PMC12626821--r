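# melseg

Automatic segmentation of facial melasma (chloasma) is hard for exactly the
reasons dermatologists find the lesions easy to miss in photographs: the
patches are low-contrast brown on brown, their borders are blurred and
irregular, and clinical photographs add illumination gradients and specular
reflections on the skin. `melseg` implements **HHBSNet**, a lightweight
multi-class segmentation network designed for this problem, together with its
full training and evaluation protocol — all in pure R, including the
convolution and backpropagation engine, so the package has no deep-learning
framework dependency.

The package is aimed at researchers in quantitative dermatology and
biological image analysis who want a transparent, fully inspectable reference
implementation of the architecture and its evaluation pipeline.

## The model

Input images are segmented into six classes:
`BACKGROUND (0), ET forehead (1), HHB melasma lesion (2), XB chin (3),
LF left face (4), RF right face (5)`.

The network is: backbone (four feature levels) → **infusion** of the first
and last levels (bilinear upsample, concatenate, 1×1 conv) → **GCSA** →
**MCF** → **global feature fusion** → 1×1 classifier → bilinear upsampling →
per-pixel softmax.

**GCSA (global channel–spatial attention).** With input `F ∈ R^{C×H×W}`:

    F_channel = σ(MLP(Permute(F))) ⊙ F          (per-pixel C → C/4 → C MLP)
    F_shuffle = ChannelShuffle_4(F_channel)     (reshape–transpose–flatten)
    F_spatial = σ(BN(Conv7×7(ReLU(BN(Conv7×7(F_shuffle)))))) ⊙ F_shuffle

**MCF (multi-scale cavity fusion).** Five parallel branches — a 1×1 conv,
three depthwise-separable 3×3 convolutions at dilation rates **6, 12, 18**,
and a global-average-pooling branch — are concatenated to `5C` channels and
projected back to `C`. The merged map `F` is then calibrated:

    w_c = σ(FC2(ReLU(FC1(avgpool(F)))))     F_c' = w_c ⊙ F
    w_s = σ(Conv1×1([AvgPool_c(F); MaxPool_c(F)]))   F_s' = w_s ⊙ F
    F_out = Conv1×1(F_c' + F_s' + F)

**Objective.** A hybrid of cross-entropy and focal loss,

    L = λ·L_CE + (1−λ)·L_FL,   L_CE = −Σ y_i log p_i,
    L_FL = −α (1−p_i)^γ y_i log p_i

with defaults λ = 0.5, α = 0.25, γ = 2, optimized by SGD with momentum 0.9
and a step-decayed learning rate.

**Evaluation.** Pixel confusion matrices; mean IoU, accuracy, F1, mean
recall, precision, per-image lesion Dice, specificity; one-vs-rest ROC/AUC;
`mean ± sd` aggregation over repeated runs and paired t-tests between models.

Because clinical melasma photographs are private data, the package ships a
synthetic facial-lesion scene generator (`synth_face_scene()`) that emulates
the documented challenges — low-contrast irregular blobs with blurred
boundaries inside a face-shaped region map, illumination gradients, specular
highlights — so every experiment in the package is reproducible from code.

## Worked example

```r
library(melseg)

# 8 synthetic 64x64 scenes; tiny 4-level backbone
ds  <- synth_dataset(8, scene_spec(image_size = 64, seed = 42))
cfg <- tiny_network_config()
tc  <- train_config(epochs = 500, batch_size = 8, lr = 0.02,
                    lr_factor = 0.5, lr_period = 200,
                    loss = loss_config(lambda = 0.5, alpha = 0.25, gamma = 2),
                    augment = FALSE, seed = 7, target_train_miou = 0.9)
res <- train(tc, cfg, ds)
tail(tidy(res), 1)
#> # A tibble: 1 × 6
#>   epoch    lr train_loss train_miou val_loss val_miou
#>   <int> <dbl>      <dbl>      <dbl>    <dbl>    <dbl>
#> 1    87  0.02     0.0538      0.900       NA       NA

ev <- evaluate(list(params = res$params, config = cfg), ds)
glance(ev)[, c("miou", "acc", "f1")]
#> # A tibble: 1 × 3
#>    miou   acc    f1
#>   <dbl> <dbl> <dbl>
#> 1 0.867 0.955 0.927
```

Training reaches a mean IoU of 0.90 (training-mode statistics) within 87
full-batch gradient steps; `evaluate()` then recomputes the full metric
protocol — confusion matrix, the seven metrics, per-image lesion Dice,
one-vs-rest AUCs — from the trained parameters in inference mode (running
batch-norm statistics, hence the slightly lower 0.867). `autoplot(res)` draws the
loss/mIoU curves, `plot_mask()` renders masks, and `predict_overlay()`
produces lesion-boundary overlays (red) with the face contour (green) plus
per-class probability heatmaps.

A command-line front end with `synth`, `train`, `evaluate` and `predict`
subcommands is installed at `inst/cli/melseg`.

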