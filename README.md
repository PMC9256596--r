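# thgqc — quality-filtered deep-learning classification of THG microscopy images

Third harmonic generation (THG) microscopy images fresh, unstained brain
tissue within seconds: myelinated fibers appear as bright curves, cell
bodies as dark holes with dimly visible nuclei. Because glioma
infiltration raises cell density, a binary classifier over THG images can
flag tumor tissue fast enough to assist a neurosurgeon during resection.
`thgqc` implements the full tissue-to-inference pipeline for this task,
for microscopists and image-analysis researchers who want every stage
testable end-to-end without patient data:

* **Frequency-domain quality control** — the noise-detection step at the
  heart of the pipeline. For each image the 2-D power spectrum of the
  mean-subtracted pixels is computed, and the *tail* — coefficients with
  normalized radial frequency `r ≥ 1 − f` (e.g. the top 20%) — is
  summarized by seven descriptive statistics. The exclusion rule uses the
  Pearson kurtosis `m₄/m₂²` (3 for a Gaussian): training images whose
  tail kurtosis exceeds a cutoff are dropped. Deep, signal-starved
  acquisitions concentrate spectral energy in a few outlying tail
  coefficients, so their kurtosis rises — the signature the filter
  detects. Test sets are never filtered.
* **A six-block fully-convolutional classifier (FCN)** — four blocks of
  5×5 convolution + batch norm + ReLU + 2×2 max pooling
  (32/64/128/256 channels), a 64-channel 1×1 block, and a single-channel
  1×1 convolution with global average pooling and a sigmoid: 1,092,993
  convolution parameters, L2-regularized kernels (factor 0.01),
  He-uniform initialization, and — having no dense layers — dynamic
  input sizes from 16 px up. Implemented from scratch on
  Rcpp/RcppArmadillo GEMM kernels; no deep-learning framework required.
* **Monte-Carlo cross-validated training** — case-level random splits
  (validation = 1 negative + 4 positive cases), per-epoch minority
  oversampling to exact class balance, unique per-sample augmentation
  (contrast, brightness, rotation), padded batches of 32, SGD with
  momentum 0.9, learning-rate × 0.2 on validation-loss plateaus, early
  stopping, and checkpointing at the lowest validation loss.
* **Youden-calibrated evaluation** — ROC/AUC (≡ Mann-Whitney
  concordance), step-interpolated average precision with its prevalence
  no-skill baseline, the threshold maximizing Youden's
  J = sensitivity + specificity − 1, and vertical mean ± variance curve
  aggregation across the model ensemble.
* **Sliding-window overlays** — per-pixel averaged score maps over
  stitched mosaics, binarized into normal/tumor masks and scored against
  reference masks with per-class Jaccard (IOU) indices.
* **A phantom generator** — synthetic THG-like images, depth-degraded
  z-stacks, tumor-boundary mosaics and multi-case weak-label datasets
  with known ground truth, emulating the imaging appearance (fibers,
  dark cells, detector noise chain) so the whole pipeline runs and is
  validated without any acquisition hardware.

## Worked example

Generate a phantom dataset, rank its images by spectral-tail kurtosis,
and watch the filter separate clean from depth-degraded images:

```r
library(thgqc)

p <- phantom_params(height = 256L, width = 256L)
zs <- render_zstack(p, "normal", n_slices = 6L, depth_step_um = 15, seed = 1)
round(stack_kurtosis_profile(zs, freq_frac = 0.2), 1)
#> [1]   8.0   8.9  12.1  36.0 190.1  27.0
```

The first (shallow, signal-rich) slice sits near the dense-noise floor
(kurtosis ≈ 9); with depth the THG signal decays and the sparse
electronic noise dominates the spectrum tail, driving kurtosis far above
10 — the deep slices are exactly the ones a cutoff of 10–12 removes
from a training set.

Train the classifier on separable phantoms and segment a boundary mosaic:

```r
study <- learnability_study(seed = 1)       # a few minutes on one core
study$val_auc_raw
#> [1] 0.9930556

ov <- boundary_overlay_study(study$fit, seed = 1)
ov$iou
#> <IOU normal 0.625, tumor 0.727>
```

An AUC of 0.99 on held-out phantoms says the architecture learns the
density signal; the overlay IOUs say the sliding-window map, binarized
at the model's Youden threshold, recovers the normal/tumor boundary of
a mosaic whose ground truth the generator knows (at ~2.5 vs. ~10
expected cells per window the realized densities fluctuate, so the
recovered boundary is serviceable rather than pixel-perfect — see the
methods vignette).

The full condition-sweep experiment (`condition_trend_study()`) shows the
interaction that motivates the quality filter: moderate kurtosis
exclusion matches or beats training on the raw pool, while an over-strict
cutoff that removes > 80% of the data falls clearly below it.

A whole-pipeline run from one YAML config (simulate → preprocess → qc →
train → evaluate → segment) is `run_pipeline(experiment_config(...))`, or
from a shell via the thin CLI in `inst/cli/thgqc`.

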