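# ramanotype

Chemometric profiling and quantification of tomato carotenoids from
handheld Raman spectra.

Tomato fruit colour is set by carotenoids, and the Raman nu1 (C=C
stretch) band is a fingerprint for which one dominates: it peaks near
1519 cm^-1 for all-trans-lycopene, 1523 cm^-1 for tetra-cis-lycopene and
1528 cm^-1 for beta-carotene, next to common bands at 1007 and 1158
cm^-1. `ramanotype` is aimed at spectroscopists and breeders who want a
tested, reproducible implementation of the standard analysis chain for
such spectra:

* **Simulation** — seeded surface Raman spectra for seven
  carotenoid-profile classes (Lorentzian bands, polynomial baseline,
  multiplicative scatter, detector noise, replicate structure), plus a
  Beer–Lambert utility `A/(epsilon * l) -> mg/100 g` for UV-Vis reference
  values.
* **Preprocessing** — SNV, Savitzky–Golay smoothing/derivatives, region
  selection, leakage-free mean centering, composable via
  `preprocess_plan()`.
* **SIMCA** — one PCA model per class with cross-validation-calibrated
  class admission, interclass distances
  `D(a,b) = sqrt((s_ab^2 + s_ba^2)/(s_aa^2 + s_bb^2)) - 1`,
  discriminating power and Mahalanobis/residual outlier diagnostics.
* **PLS1** — NIPALS with leave-one-out cross-validation (`SECV`, `r_cv`),
  latent-variable selection and external validation (`SEP`, `r_pred`).
* **MLP** — a from-scratch feedforward network (ReLU hidden layers,
  softmax/cross-entropy or ReLU/MSE head) with inverted dropout, ADAM,
  early stopping, sliding-window spectral variable selection and random
  hyperparameter search; gradients are verified against finite
  differences in the test suite.

## Worked example

```r
library(ramanotype)

# classification benchmark: 106 samples over seven classes, 3 replicates
rep_cls <- run_classification(classification_config(seed = 1))
rep_cls
#> <evaluation_report>
#>   SIMCA held-out accuracy: 95.2%
#>   ANN test accuracy: 100.0% (topology 62-79-130-7)
#>   min interclass distance: 4.97
#>   discriminating-power peak: 1464.8 cm-1

# lycopene calibration benchmark: 58 samples, 1.8-21.5 mg/100 g
rep_q <- run_quantification(quantification_config(seed = 1))
rep_q
#> <evaluation_report>
#>   lycopene PLSR: a = 1, r_cv = 0.982, SECV = 1.01, r_pred = 0.991, SEP = 0.87 mg/100 g
#>   lycopene ANN:  r = 0.984, RMSE = 1.23 mg/100 g (topology 62-209-66-1)
```

Reading the numbers: the SIMCA model correctly assigns 20 of the 21
held-out samples at this seed (the odd one out is admitted to no class —
samples are only assigned to classes whose residual test they pass), the
best network classifies its test split perfectly, and every pair of the
seven classes is separated by an interclass distance above 3 (the
conventional "well-separated" threshold; the closest pair involves nu1
bands one detector pixel apart). The
discriminating-power peak is reported for derivative-filtered spectra,
where band information is spread across the 25-point filter window — on
SNV-only spectra it falls at the nu1 shift itself. For calibration, the
leave-one-out choice lands on a single latent variable (the simulator's
concentration→amplitude map is linear), with an external standard error
of prediction of ~0.9 mg/100 g against a 1.8–21.5 mg/100 g working
range; the network regressor reaches the same noise floor, which is set
by the multiplicative scatter surviving replicate averaging
(0.15/sqrt(3) ≈ 8.7%).

Lower-level entry points (`generate_dataset()`, `pp_fit()`,
`simca_fit()`, `pls_loo_cv()`, `mlp_train()`, `mlp_search()`, ...) expose
each stage separately; see the vignette in `vignettes/` for the models,
conventions and design decisions.

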