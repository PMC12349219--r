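# gazefusion

Gaze-guided multimodal fusion for multilabel abnormality detection in chest
radiographs, with built-in explanation scoring and a synthetic phantom
generator so the whole pipeline runs end-to-end on a laptop CPU with no
external data.

Radiologists' fixations mark where diagnostic evidence sits. This package

* renders **fixation heatmaps** `H_Eye` from gaze tables (Gaussian kernel
  density, duration-weighted, max-normalized, blue-to-red colormap);
* performs **early fusion**, stacking the grayscale image and the heatmap's
  RGB rendering into a 4-channel input
  `I_Multi = Concat(I_CXR, H_Eye)`;
* applies a learned **attention gate** — two 1×1 convolutions producing
  sigmoid scores `A = σ(W2 * ReLU(W1 * F + b1) + b2) ∈ [0,1]` that multiply
  the input elementwise — before a **shared CNN backbone** and a sigmoid
  multilabel head `P = σ(W_fc · F_backbone + b_fc)`;
* explains predictions with **Grad-CAM**,
  `L^c = ReLU(Σ_k α_k^c A^k)` with `α_k^c = (1/Z) Σ_ij ∂y^c/∂A^k_ij`,
  and scores explanations against expert ellipse ROIs by
  `mIoU = (1/N) Σ_i IoU_i`;
* stress-tests robustness by injecting **striped line noise** into the
  fixation channels at test time and sweeping classification AUC across
  noise levels;
* generates seeded **phantom datasets** — lesion blobs with exact ellipse
  ROIs, six texture-coded finding classes, multilabel targets, and
  expert-like gaze concentrated on lesions — emulating the statistical
  structure the method assumes.

Training runs on the package's own compact, fully seeded CNN engine
(RcppArmadillo convolutions, analytic gradients, Adam + weight decay on
multilabel binary cross-entropy); no deep-learning framework is required.

## Worked example

```r
library(gazefusion)

# a seeded phantom cohort: images, labels, ellipse ROIs, gaze tables
ds <- generate_phantom_dataset(
  phantom_config(n_samples = 600, seed = 7, on_lesion_fraction = 0.9))
sp <- attr(split_dataset(seq_len(600), seed = 7), "indices")

# fuse each image with its own gaze heatmap and train
inp <- build_inputs(ds, "fusion")
model <- build_fusion_model(seed = 7)
fit <- train_model(model, inp$x[, , , sp$train, drop = FALSE],
                   inp$y[sp$train, ],
                   config = train_config(epochs = 30, learning_rate = 2e-3,
                                         seed = 7))

# held-out multilabel metrics
probs <- model_predict(fit$model, inp$x[, , , sp$test, drop = FALSE])
met <- classification_metrics(probs, inp$y[sp$test, ])
print(met$macro)
#>  accuracy precision    recall        f1       auc
#> 0.7722222 0.6422222 0.4243848 0.4266334 0.7831501

# noise robustness of the fixation channels
run_noise_sweep(fit$model, inp$x[, , , sp$test, drop = FALSE],
                inp$y[sp$test, ], levels = c(0, 0.1, 0.5),
                spec_template = noise_spec(0, stripe_thickness = 2, seed = 7))
#>   level macro_auc
#> 1   0.0 0.7831501
#> 2   0.1 0.7862473
#> 3   0.5 0.7715339
```

Macro AUC ≈ 0.78 says the fused model ranks held-out positives well above
negatives on average across the six finding classes. The sweep probes how
much of that ranking survives when striped noise erases 10% and then 50% of
the fixation evidence; a single seed fluctuates at mild noise (as here at
the 10% level), while the mean over the five-seed study declines
monotonically (0.814 → 0.808 → 0.775 with `scripts/acceptance.R --seed 1`).

Explanations, on a single-finding phantom trained to saturation:

```r
ev <- evaluate_explanations(fit1$model, test_ds, x_test)
ev$hit_rate   # fraction of CAM argmaxes inside the planted ROI
ev$miou       # CAM-vs-ROI mean IoU at threshold 0.5
```

A command-line wrapper for the whole pipeline (simulate / heatmap / train /
noise-test / evaluate / explain-eval) ships in `inst/cli/gazefusion.R`.

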