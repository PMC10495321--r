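# leafnitro

Non-destructive estimation of leaf nitrogen (N) content from ordinary RGB
photographs of single leaves on a white board. N supply changes a leaf's
chlorophyll content, and with it the colour and the uniformity of the leaf
surface; `leafnitro` turns those signals into a cross-validated N
prediction for crop stages such as sugarcane tillering and elongation. It
is aimed at researchers in image-based crop phenotyping who want a fully
seeded, testable pipeline rather than a one-off script.

The chain, end to end:

* **Illumination correction** — multi-scale retinex with colour
  restoration (MSRCR): per channel,
  `MSR_i = Σ_k w_k [log(I_i + ε) − log(S_ki + ε)]` over Gaussian surrounds
  `S_ki` at scales 15/80/250 px, times the restoration factor
  `C_i = β log(α I_i / ΣI_j)`, then a per-channel percentile stretch. The
  surround is a Gaussian-weighted local plane fit, so affine illumination
  fields are removed exactly.
* **Segmentation** — Otsu threshold on distance-from-white, morphological
  cleanup, largest connected component.
* **Features** — 24 colour features (RGB indices, normalised rgb, HSV,
  CIELAB) from the masked channel means, plus 5 gray-level co-occurrence
  matrix statistics (ASM, IDM, CON, ENT, COR) averaged over the 0°, 45°,
  90°, 135° azimuths.
* **Selection** — Pearson screening (|r| > 0.7 against N) and blockwise
  PCA with Kaiser (eigenvalue > 1) retention; six input variants from
  CF-SCT to C-T-PCA.
* **Regression** — MLR, PLS, SVR, BPNN and random forest under nested
  5-fold cross-validated grid search, and a stacking fusion model (SFM):
  PLS/SVR/BPNN bases whose out-of-fold predictions train a BPNN
  meta-learner. Reported metrics are fold-mean R², RMSE and MAPE.

Because no public dataset accompanies the problem, the package includes a
seeded synthetic leaf generator (elliptical leaves whose colour and
mottling are statistically coupled to a latent N value, corrupted by
pixel noise and an illumination ramp, with ground-truth masks). It is the
canonical input for the tests and the acceptance script.

## Worked example

```r
library(leafnitro)

ds  <- generate_dataset(generator_config(stage = "tillering", seed = 11))
ext <- dataset_features(ds)          # MSRCR + segmentation + 29 features

sel <- fit_selectors(ext$features, ext$n)
print(sel$screen)
print(pca_table(sel$pca_cf, 3))

res <- evaluate_variant(ext$features, ext$n, "C-T-PCA", "SFM",
                        k = 5, seed = 5)
print(res)
print(round(res$per_fold, 4))
```

```
<correlation_report> threshold |r| > 0.7: 22 of 29 selected
  block PC eigenvalue       VCR     CVCR
1    CF  1 18.4041115 76.683798 76.68380
2    CF  2  4.8654686 20.272786 96.95658
3    CF  3  0.6425704  2.677377 99.63396
<cv_result> C-T-PCA / SFM (k = 5): R2 = 0.9651, RMSE = 0.0763, MAPE = 0.0405
      R2   RMSE   MAPE
1 0.9483 0.0939 0.0476
2 0.9665 0.0708 0.0348
3 0.9931 0.0397 0.0237
4 0.9556 0.0965 0.0605
5 0.9617 0.0806 0.0358
```

Reading this: 22 of the 29 features correlate with the latent N at
|r| > 0.7; the first three colour principal components carry 99.6% of the
colour-block variance; and the stacking model explains ~97% of the
held-out N variance (fold-mean R² 0.9651) with a root-mean-square error
of 0.076 N units and a 4% mean absolute percentage error.

A full stage × variant × model sweep is one call
(`run_experiment(experiment_config(...))`) or, from a shell, the thin
wrapper `inst/scripts/leafn run-all --out runs/demo --seed 1`.

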