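---
title: "Gaze-guided multimodal fusion: models, phantoms, and design choices"
author: "gazefusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-guided multimodal fusion: models, phantoms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazefusion)
```

## The method

Radiologists' eye movements encode where diagnostic evidence sits in a chest
radiograph. This package implements a gaze-guided fusion pipeline that turns
that signal into a model input and then interrogates what the model learned:

1. **Fixation heatmap.** Each image's fixation table (x, y, duration) becomes
   a spatial density `H_Eye`: a sum of isotropic Gaussian kernels centered at
   the fixations, duration-weighted by default, max-normalized to [0, 1], and
   rendered through a fixed blue-to-red colormap.
2. **Early fusion.** The grayscale radiograph `I_CXR` and the heatmap's RGB
   rendering are stacked along the channel dimension into a 4-channel input.
3. **Attention gate.** Two 1x1 convolutions (channel expansion with ReLU,
   then a sigmoid score map, with optional dropout on the scores during
   training) produce per-pixel weights in [0, 1] that multiply the input —
   a learned spatial filter aligned with, but not hard-wired to, the gaze.
4. **Shared backbone and multilabel head.** A single CNN processes all gated
   channels; an affine head emits one logit per finding, converted to
   independent probabilities by a sigmoid and thresholded (default 0.5).
5. **Explanation.** Grad-CAM: gradients of a class logit with respect to a
   convolutional layer's activations are spatially averaged into weights
   `alpha_k`, the weighted activation sum is rectified, normalized, upscaled,
   and compared against expert ellipse ROIs by mean
   intersection-over-union (mIoU).
6. **Robustness.** A striped-noise protocol corrupts only the heatmap
   channels at test time (stripes of configurable thickness covering a target
   pixel fraction), and classification AUC is swept across noise levels.

## The training engine

No deep-learning framework is assumed: the package ships a compact, fully
seeded CNN engine (C++ under the hood) with exact analytic gradients —
verified in the test suite against finite differences — and Adam with L2
weight decay on multilabel binary cross-entropy. Identical configs and seeds
reproduce loss curves bit-for-bit, which the reproducibility tests rely on.

The backbone is two 3x3 convolution blocks (widths 8 and 16, ReLU, one 2x2
average pool between them) followed by **global max pooling**. Max pooling is
a deliberate choice: detecting a localized finding is a multiple-instance
problem ("does this pattern occur anywhere?"), and a max readout lets a small
lesion drive its detector channel regardless of how little area it covers.
With mean pooling, a lesion occupying a few percent of the frame contributes
a few percent of a pooled feature — at phantom scale that signal drowns in
background variation, which we confirmed empirically before settling on the
max readout. Global pooling also keeps the model resolution-agnostic.

Grad-CAM composes cleanly with this head: the gradient of a logit with
respect to the hooked layer is concentrated at each feature map's peak, so
the spatially averaged weights `alpha_k` are proportional to the head weights
— the classic class-activation-mapping regime.

Defaults for full-scale training mirror a standard fine-tuning protocol
(Adam, learning rate 5e-5, weight decay 1e-3, batch 32, 20 epochs, 80/10/10
split, seed 42). The phantom-scale studies below train the compact backbone
from scratch, for which we use learning rate 2e-3 (1e-3 to 1e-2 in the
saturation/overfitting checks) — the conventional range for small CNNs
without pretraining; the fine-tuning default would be needlessly slow there.

## The synthetic phantom

Everything is exercisable end-to-end without external data via a seeded
phantom generator that emulates the *statistical structure* the method
assumes, not radiographic realism:

* **Background**: a smooth low-frequency intensity ramp (random corner values
  in [0.30, 0.42], bilinearly interpolated) plus Gaussian pixel noise
  (sd 0.05).
* **Lesions**: additive elliptical blobs whose recorded ROI is exactly the
  blob's 2-sigma contour, so ROI masks are correct by construction. Each
  class has a characteristic texture — solid bright, annular, dark (lucent),
  speckled, horizontally striated, vertically striated — standing in for the
  distinct appearance of different findings; classes are also placed in
  characteristic image zones, mimicking anatomically localized presentation.
  Default contrast is 0.3 with major semi-axis 6–12 px on a 64 px frame:
  visible against the noise floor but faint enough that detection is the
  bottleneck, which is precisely the regime where a gaze prior can help.
* **Gaze**: each fixation targets a random lesion center with Gaussian
  scatter (sd 3 px) with probability `on_lesion_fraction` (default 0.7), and
  is otherwise a uniform distractor — the simplest null model. Durations are
  log-normal with a 250 ms median; no published distribution exists for this
  setting, so this is a placeholder, and nothing downstream depends on it
  beyond duration weighting. Start times accumulate durations plus short
  gaps.
* **Coordinates**: origin top-left, x rightward, y downward, 0-based, pixel
  centers at integer + 0.5 — stated once, used everywhere.

What passing phantom tests does *not* show: robustness to anatomy-correlated
clutter, inter-reader strategy variation, label noise, or the calibration
drift of real eye trackers. The phantom establishes that the pipeline's
machinery — fusion, gating, training, explanation, scoring — behaves as
specified, and that gaze information is used when it is genuinely
informative.

## Heatmap and preprocessing choices

* **Kernel bandwidth**: not identified by the source protocol; default
  `image_size / 25`, a one-degree-of-visual-angle surrogate common in
  saliency mapping. Configurable.
* **Max-normalization** (rather than sum-normalization) keeps the heatmap
  channel on the same [0, 1] scale as the image channel, balancing the fused
  channels. A consequence worth knowing: an all-distractor gaze map still
  peaks at 1 somewhere, so "hotspot present" alone is uninformative — models
  must read hotspot *placement* against image content.
* **Colormap**: a fixed blue→teal→amber→red lookup table with strictly
  increasing channel sums, so both hue and brightness are monotone in
  density; shipped in code for bit-exact reproducibility.
* **Preprocessing**: evaluation mode is purely geometric (bilinear resize of
  the short side, center crop); training mode adds a slight seeded Gaussian
  blur and brightness/contrast jitter (±10%). Applying the same transform to
  image and heatmap keeps the modalities registered; a registration test
  plants a fixation in a lesion and checks it stays inside the transformed
  ROI.

## Numerical and degenerate-case decisions

* Gate scores use a single broadcast channel by default (the score map is
  "attention", one weight per location); per-channel scores are a config
  switch.
* Grad-CAM backpropagates from the pre-sigmoid logit, not the probability.
* A constant (including all-zero) raw CAM normalizes to all-zero with a
  warning — never to full saturation.
* The vertical-flip step in CAM post-processing is an orientation fix for
  datasets that need it; the phantom does not, so it defaults off.
* IoU of two empty masks is defined as 1 (correctly predicted absence) but
  classes with empty reference ROIs are excluded from mIoU with a warning.
* F1 uses the direct form `2TP / (2TP + FP + FN)`; recall (and AUC) are
  undefined — reported `NA` and excluded from macro averages with a warning —
  only when a class has degenerate labels.
* Mean-and-dispersion of explanation IoU is reported both across classes and
  across images, since either convention is defensible.
* Striped noise fills stripes with the zero-density color by default
  (fixation evidence erased); a value-shuffling fill is available. Stripes
  are horizontal by default; both thickness and orientation are parameters.
  Noise is applied at test time only.

## The phantom-scale studies

The acceptance script (`scripts/acceptance.R`) and the heavyweight tests run
three studies sized for a single CPU:

* **Fusion benefit**: five seeded datasets (n = 600, 64 px, 90% on-lesion
  fixations); a fusion and an image-only model (30 epochs each) per seed;
  the comparison is held-out macro F1. Gaze should help exactly here:
  detection-limited lesions plus mostly-informative gaze.
* **Noise robustness**: the trained fusion models re-evaluated with striped
  noise (thickness 2) at levels 0, 0.10 and 0.50 on the heatmap channels;
  the mean macro AUC is expected to be nonincreasing in the noise level.
* **Grad-CAM localization**: a single-class phantom (n = 300, solid blobs at
  contrast 0.5), an image-only model trained to saturation, and two scores
  on held-out positives: the rate at which the CAM argmax lands inside the
  planted ROI, and CAM-vs-ROI mIoU compared against the untrained model.

## Known limitations

* The compact backbone is not a ResNet; no pretrained weights are involved,
  and capacity-bound behaviors (calibration, per-class balance at a fixed
  0.5 threshold) are noisier than with large pretrained models.
* The per-image split can leak patient-level information on real data where
  one patient contributes several images; splitting is per-image because the
  phantom has no patient structure.
* The no-shared-parameters baseline (two parallel backbones with feature
  concatenation) is one reasonable reading of "no shared parameters";
  alternatives exist.
* Fixation *detection* from raw tracker samples is out of scope; the package
  consumes already-extracted fixations.
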