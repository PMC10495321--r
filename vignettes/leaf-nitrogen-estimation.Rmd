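---
title: "Estimating leaf nitrogen from RGB images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf nitrogen from RGB images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafnitro)
```

## The problem

Leaf nitrogen (N) status drives fertiliser decisions in crops such as
sugarcane, but laboratory determination (acid digestion followed by
continuous-flow analysis, `n_content(m, V, M) = m V / M * 1e-3`) is slow and
destructive. Because chlorophyll content tracks N supply, the colour and
texture of a leaf photographed with an ordinary camera carry usable signal:
N-replete leaves are darker and more uniformly green; starved leaves are
paler and patchier. `leafnitro` implements the full estimation chain from a
single-leaf photograph on a white board to a cross-validated N prediction:

1. **Illumination correction** — multi-scale retinex with colour
   restoration (MSRCR);
2. **Segmentation** — classical whiteboard background removal;
3. **Features** — 24 colour features over four colour spaces and 5
   gray-level co-occurrence matrix (GLCM) texture statistics;
4. **Selection** — Pearson screening (|r| > 0.7, "SCT" sets) and blockwise
   PCA with Kaiser retention;
5. **Regression** — MLR, PLS, SVR, BPNN and random forests under nested
   5-fold cross-validated grid search, plus a stacking fusion model (SFM)
   whose meta-learner is trained on out-of-fold base predictions.

No public field dataset accompanies this problem, so the package ships a
seeded synthetic leaf generator whose statistics are coupled to a known
latent N value; it is the canonical test input for every stage, and all
empirical claims in the test suite are made against it.

## The synthetic generator: what it emulates

`generate_dataset(generator_config())` emits 60 samples per growth stage
(tillering and elongation get independent colour parameter sets), each a
single elliptical leaf on a near-white board (level 0.96), at 256×256
pixels, with:

* **latent N** drawn uniformly on [0.8, 2.2] (mass-fraction %). Uniform
  rather than normal sampling avoids giving the correlation screen
  high-leverage extremes;
* **colour link**: mean leaf sRGB is `color_base + color_slopes * N`; the
  default slopes are negative (darker with higher N), strongest in red —
  the direction expected from increasing chlorophyll absorption;
* **texture link**: a Gaussian-filtered white-noise mottle field (3 px
  correlation length) added to the leaf with amplitude `a0 + a1 N`
  (defaults 0.07 − 0.02 N), so low-N leaves are patchier. The field is
  mean-centred over the leaf, which keeps channel means *exactly* affine
  in N — the hook for the exact-recovery tests below;
* **pixel noise** (SD 0.012, truncated at ±2 SD) and a **multiplicative
  affine illumination ramp** of random direction (strength 0.25).

What the generator deliberately does not emulate: venation, specular
highlights, multi-leaf scenes, camera optics, JPEG artifacts. Passing
tests therefore demonstrate the correctness of the pipeline's mechanics
and its behaviour under controlled degradation — not field accuracy on
real sugarcane, for which the published headline numbers (e.g. SFM R² ≈
0.93/0.91 per stage) remain the external reference point.

```{r generator, eval = FALSE}
ds <- generate_dataset(generator_config(stage = "tillering", seed = 1))
write_dataset(ds, "leaves/")      # PNGs + masks + manifest.csv
```

## Illumination correction

MSRCR computes, per channel, `MSR = sum_k w_k (log(I + eps) - log(S_k +
eps))` over surrounds `S_k` at scales 15, 80 and 250 px, multiplies by the
chromatic restoration factor `C = beta log(alpha I / (R + G + B))`
(alpha = 125, beta = 46), and applies a per-channel 1–99 percentile
stretch to [0, 1]. These constants follow the canonical MSRCR literature
and are all exposed in `msrcr_params()`.

One design choice is ours: the surround is a **Gaussian-weighted local
plane fit** (normalised convolution with first-order moments) rather than
a plain Gaussian blur. A plain blur departs from the image wherever the
kernel overhangs the boundary — for surround scales comparable to the
image this is everywhere — leaving large residuals under a purely linear
illumination field. The local plane fit reproduces affine signals exactly
at every pixel, so a constant-reflectance leaf board under a linear ramp
maps to a constant: the generator's illumination model is removed exactly,
and smooth nonlinear fields are removed to first order. Degenerate
(constant) outputs are mapped to 0.5 and flagged in the image metadata
rather than stretched, which would amplify numerical noise.

Numerical notes: natural logs with floor `eps = 1e-6`; kernels truncated
at min(3.5 sigma, half the smaller image dimension); all scales share one
zero-padded FFT plan, and the image-independent moment geometry is cached
per image size, which makes a 256×256 correction about a second of work.

## Segmentation

The imaging protocol — one leaf on a white board — makes background
removal classical: Otsu's threshold on the per-pixel Euclidean distance
from white, 3×3 morphological closing, hole filling, and retention of the
largest connected component (`segment_leaf()`). The contract is the same
as a trained salient-object detector would provide, and externally
produced masks can be injected via `as_leaf_mask()`. On the generator's
defaults the mask IoU against ground truth exceeds 0.95 with or without
the illumination ramp; an image with no component above 1% area raises a
"no leaf found" error.

## Features

`color_features()` reduces the masked region to its three channel means
and derives the remaining 21 indices from them (ratio and difference
indices, chromatic coordinates r, g, b with gr = g − r etc., HSV, CIELAB
under D65). Ratios are guarded with eps = 1e-6 and H is stored as
degrees/360 so every feature lives on a comparable scale for PCA. We
compute ratios *of means* rather than means of per-pixel ratios, treating
the features as functions of the region's summary colour.

`texture_features()` quantises the masked Rec. 709 luminance to 64 gray
levels over the foreground min–max range, builds symmetric unit-offset
GLCMs at 0°, 45°, 90° and 135°, and averages the five Haralick statistics
over the angles: energy (ASM), homogeneity (IDM), contrast (CON), entropy
(ENT, natural log; base configurable) and correlation (COR, flagged
undefined when a marginal SD collapses, as on a constant leaf). Level
count, offset and the luminance channel are conventional choices — 64
levels balances co-occurrence density at typical leaf sizes — and are
arguments, not constants. A brute-force pair-enumeration oracle in the
test suite pins the implementation to its definition at 1e-12.

## Selection

`pearson_screen()` keeps features with |r| > 0.7 against N (the threshold
applies to the magnitude: a strongly negative correlate is as useful as a
positive one). `fit_pca()` standardises each block and eigendecomposes
its correlation matrix; `kaiser_retain()` keeps components with
eigenvalue > 1 (floored at one component, with a warning). Colour and
texture blocks are reduced *separately* and their retained scores
concatenated ("C-T-PCA"), preserving the block structure of the
variance-contribution table semantics; the loading sign convention
(largest-magnitude entry positive) makes results machine-independent.

Six input variants feed the regression layer: CF-SCT, TF-SCT, CTIF-SCT
(the union), CF-PCA, TF-PCA and C-T-PCA.

## Regression layer and fold hygiene

All families share one train/predict surface (`train_model()`): PLS, SVR
and BPNN inputs *and targets* are min–max scaled to [−1, 1] with scalers
fitted per training set and inverted before metrics; MLR and RF run on
raw features. The BPNN is an in-package multilayer perceptron (arbitrary
hidden layers; identity/logistic/tanh/relu; lbfgs/adam/sgd; L2 penalty
1e-4; up to 15 000 epochs), because no installed network package exposes
this activation/solver grid; its backpropagation gradient is verified
against finite differences in the tests. PLS1 is NIPALS, cross-checked
against an independent reference implementation. SVR delegates to a
standard epsilon-SVR (C = 1; kernel and gamma searched), RF to a standard
random forest (ntree and terminal-node size searched; the
minimum-split-size parameter of other implementations has no counterpart
here and maps onto node size).

`evaluate_variant()` enforces the leakage discipline: in every outer fold
the screen, the PCA models, the scalers and the hyperparameter choice
(inner cross-validated `grid_search()`, best mean R², ties by RMSE then
grid order) are refit on the training rows only. An audit log
(`audit_start()`/`audit_stop()`) records the sample indices of every fit
so tests can prove no fit ever saw held-out rows. A `prefit_selectors` flag
instead fits selectors once on all data, matching a
selection-before-modelling workflow, for users who want that comparison.

The stacking fusion model (`stacking_fit()`) trains PLS, SVR and BPNN
bases; each base's out-of-fold predictions over 5 folds form the (m, p)
meta-feature matrix on which a BPNN meta-learner (default: one hidden
layer of 10) is trained; bases are refit on all training data for
inference — the standard stacking arrangement. Reported metrics are
fold-mean R², RMSE and MAPE in the original units, and are labelled as
fold means.

### Default grids and problem sizes

Nested cross-validation multiplies every grid cell by ~25 fold-fits, so
the package defaults are deliberate desk-scale reductions of the stated
search ranges: BPNN defaults to a 6-cell grid (one hidden layer of 10 or
50; identity/tanh/relu; lbfgs), with `bpnn_grid("lattice")` (144 cells,
covering all four activations, three solvers and 1–3 layers) and
`default_grid(family, full = TRUE)` available for denser sweeps. The
test suite and the acceptance script run 60 samples per stage at
256×256 — the generator's default study conditions — with 5 outer folds;
the suite repeats the model comparison over 5 model seeds.

## Known limitations

* The generator's colour–N link is affine by construction; real canopies
  saturate. The exact-recovery tests (cross-validated MLR R² = 1 on
  noise-free data) validate plumbing, not biology.
* The percentile stretch inside MSRCR normalises each image's contrast,
  so absolute reflectance information survives only relative to the
  white board; colour-checker calibration is out of scope.
* GLCM features are computed on luminance only; per-channel texture,
  wavelet/LBP/Gabor descriptors are not implemented.
* MAPE is undefined at zero targets and is flagged, not imputed; COR is
  undefined on texture-free regions and excluded from the angle average.
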