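# rasarstack

Similarity-augmented QSAR (q-RASAR), ARKA and stacked-PLS modeling of acute
aquatic toxicity, built for the multispecies salmon pLC50 endpoint.

## What this package is for

Regulatory ecotoxicology needs pLC50 predictions
(pLC50 = −log10 LC50 in mol/L; higher = more toxic) for compounds that have
never been tested on fish. `rasarstack` implements the full modeling
pipeline behind a published multispecies salmon model family, for
cheminformaticians and risk assessors who want to rebuild, audit or reuse
it:

* **Structure input and curation** — CSV / SMILES / SDF reading, salt and
  metal removal, duplicate merging on canonical SMILES, LC50 (mg/L) →
  pLC50 conversion.
* **Descriptors** — the six 2D descriptors of the published equations:
  H-053, NsssCH, B02[N-N], B02[S-S], B03[N-O] and the Wildman–Crippen
  LOGP99.
* **Data preparation** — variance/correlation pretreatment, four train/test
  division schemes (activity-based, Kennard–Stone, Euclidean, k-medoid),
  best-subset and genetic-algorithm feature selection.
* **Read-across** — Gaussian / Laplacian / inverse-distance similarity
  kernels, close-source selection, grid hyperparameter optimization on a
  sub-split of the training set.
* **RASAR descriptors** — the 18-column similarity/error block of each
  query's close-source neighbourhood, fused with the structural block
  ("data fusion").
* **ARKA** — supervised two-group dimensionality reduction with
  activity-cliff and confidence diagnostics on the ARKA_1/ARKA_2 plane.
* **Models** — single-response NIPALS PLS, MLR, equal-prior LDA,
  bagged-tree classification, and the 1-LV PLS stacking meta-model
  `pLC50 ~ QSARpred + RASARpred + ARKApred + Hybridpred`.
* **Validation** — R², Q²(LOO), Q²F1/Q²F2, Lin's CCC, MAE, RMSEp,
  Y-randomization with intercept criteria (R²Y < 0.3, Q²Y < 0.05), DModX
  applicability domain at 99% confidence, and good/moderate/bad
  prediction-quality categories.
* **Frozen published predictor** — the six published salmon equations with
  their printed coefficients, scoring new compounds from SMILES alone
  through the QSAR and LDA routes.

The core statistical objects are ordinary S3 models: `fit_pls()`,
`fit_mlr()`, `fit_lda()`, `fit_bagged_trees()`, `read_across()` and
`stack_models()` all return classed objects with `print`, `coef`,
`predict`, `fitted` and `residuals` methods as applicable.

Chemistry (SMILES/SDF parsing, canonicalization, logP) is delegated to
OpenBabel through the Bioconductor package ChemmineOB; everything else is
base R plus MASS, cluster and randomForest.

## Worked example

The original 106-compound salmon dataset is available only on request, so
the example runs on the package's synthetic study conditions (106 compounds,
6 descriptors, linear response + noise — the dimensions of the real study):

```r
library(rasarstack)

d  <- gen_regression_dataset(n = 106, p = 6, noise_sd = 0.3, seed = 1)
sp <- split_data(d$x, d$y, "activity", test_fraction = 26/106)
sp
#> <split_dataset> method=activity: 80 train / 26 test

tr   <- rownames(d$x) %in% sp$train
qsar <- fit_pls(d$x[tr, ], d$y[tr], n_lv = 3)
qsar
#> <pls_model> 6 descriptors, 3 latent variable(s), n = 80
#> Coefficients (original scale):
#> (Intercept)          x1          x2          x3          x4          x5
#>     5.32117     1.00698    -0.98889     0.98882    -0.97866     0.94642
#>          x6
#>    -0.97362

loo <- loo_crossval(function(x, y) fit_pls(x, y, 3), d$x[tr, ], d$y[tr])
regression_metrics(d$y[tr], fitted(qsar), loo,
                   d$y[!tr], predict(qsar, d$x[!tr, ]))
#> <metric_report>
#>       R2   Q2_LOO  MAE_LOO    Q2_F1    Q2_F2      CCC MAE_test    RMSEp
#>   0.9849   0.9819   0.2958   0.9830   0.9829   0.9910   0.2539   0.3235
#> n_train = 80, n_test = 26
```

The generating model has unit coefficients of alternating sign and an
intercept of 5.4; the fitted PLS recovers them to within the noise, and the
external statistics (Q²F1/Q²F2 ≈ 0.98 at noise SD 0.3) quantify how much of
the response the model explains on the held-out activity-split test set.

Scoring an untested pesticide with the frozen published equations:

```r
res <- predict_from_smiles("CNC(=O)CSP(=S)(OC)OC")   # dimethoate
round(res$descriptors, 4)
#>    H-053   NsssCH B02[N-N] B02[S-S] B03[N-O]   LOGP99
#>   0.0000   0.0000   0.0000   1.0000   0.0000   2.0244
res$plc50_qsar
#> [1] 6.5803
res$class_lda
#> [1] "toxic"
```

The S=P–S motif of dimethoate switches on B02[S-S], whose +2.13 coefficient
drives the high predicted toxicity — the mechanistic reading of the model.

A thin command-line front end over the same functions ships in
`inst/cli/rasarstack.R` (subcommands `curate`, `descriptors`, `split`,
`ra-optimize`, `predict`, `eval`, `synth`).

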