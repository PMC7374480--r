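---
title: "Carotenoid phenotyping from handheld Raman spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carotenoid phenotyping from handheld Raman spectra: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanotype)
```

## The problem

Tomato fruit colour is driven by carotenoid pigments, and breeders want a
fast, non-destructive way to tell *which* carotenoid dominates a fruit and
*how much* of it there is. Carotenoids are strong Raman scatterers: their
conjugated polyene chain produces an intense C=C stretching band (the
so-called nu1 band) near 1520 cm^-1 whose exact position shifts with chain
length and cis/trans isomerisation. On a handheld 1064 nm instrument the
nu1 band sits near 1519 cm^-1 for all-trans-lycopene (red fruit), 1523
cm^-1 for tetra-cis-lycopene (tangerine types) and 1528 cm^-1 for
beta-carotene (orange types), on top of bands at 1007 and 1158 cm^-1 that
all carotenoids share. `ramanotype` implements the full analysis chain
around this diagnostic feature:

* a seeded simulator of surface Raman spectra for seven carotenoid-profile
  classes,
* the standard pretreatments (SNV, Savitzky-Golay derivatives, mean
  centering, region selection),
* SIMCA classification with interclass distances, discriminating power and
  outlier diagnostics,
* PLS1 calibration of pigment concentration with leave-one-out
  cross-validation, and
* a from-scratch multilayer perceptron (classification and regression)
  with dropout, ADAM and early stopping, plus sliding-window spectral
  variable selection.

## The simulator: what it emulates and what it does not

No public dataset accompanies this application, so every model is
exercised on simulated spectra whose statistical structure matches what
the chemometric pipeline assumes about fruit-surface measurements.

A spectrum on the default 512-point axis (200-2500 cm^-1, linear in
wavenumber) is

```
I(w) = s * ( sum_c conc_c * sum_b amp_b * L(w; center_b, fwhm_b) + B(w) ) + e(w)
```

with `L` a unit-height Lorentzian (the standard Raman line shape), `B` a
random polynomial baseline (order 2, positive by construction) standing in
for fluorescence and surface effects, `s ~ N(1, 0.15)` a per-spectrum
multiplicative scatter factor, and `e` additive Gaussian detector noise
(sd 0.215 counts, i.e. 1% of the largest nu1 amplitude). Concentration
maps to band amplitude with unit slope, which makes calibration recovery
exactly testable. Three replicate spectra per sample share concentrations
but not noise, mirroring triplicate surface scans that are averaged before
modelling.

Class recipes follow the seven observed profiles: high all-trans-lycopene
(floored at 8 mg/100 g — the class means fruit where lycopene is *high*),
lycopene plus beta-carotene, lycopene plus gamma-carotene, beta-carotene
(1.6-9.5 mg/100 g), beta-carotene plus anthocyanins, tetra-cis-lycopene,
and a low-carotenoid class whose spectra are baseline and noise only.
Quantification datasets are a different population: *analyte-dominant*
fruit spanning the full UV-Vis reference range (lycopene 1.8-21.5,
beta-carotene 1.6-9.5 mg/100 g), provided by `quantification_recipe()`.

Several recipe constants are package defaults rather than literature
facts, chosen once and frozen:

* gamma-carotene's nu1 is placed at 1516 cm^-1 (no consensus position at
  this excitation; it must sit below 1519 to reflect its longer effective
  conjugation than beta-carotene's).
* The anthocyanin signature is modelled as an aromatic ring-stretch
  doublet at 1601/1630 cm^-1 with 16 cm^-1 width. A single very broad band
  would essentially vanish under a 25-point second derivative (curvature
  scales with amplitude/width^2), leaving the anthocyanin class
  spectrally degenerate with pure beta-carotene — unlike the clearly
  separated classes seen in real fruit.
* Composite classes draw their secondary component from a floored range
  (4-9.5 mg/100 g, with lycopene 6-15): a "lycopene + beta-carotene"
  fruit with vanishing beta-carotene is chemically indistinguishable from
  the pure class, and class assignments in practice come from
  chromatography of fruit where both pigments are substantial. The
  tetra-cis class is floored at 4 mg/100 g for the same reason (it is by
  definition the *dominant* pigment there), the beta-carotene classes at
  3 mg/100 g, and the high-lycopene class at 8 mg/100 g (low-pigment
  fruit are the low-carotenoid phenotype, not faint members of the
  pigmented classes). These
  floors are the calibration that makes the simulated classes behave like
  the chromatography-confirmed classes of real panels — without them the
  composite and dominant classes degenerate into their pure neighbours at
  range corners, a geometry no supervised classifier can resolve.
* `baseline_scale = 2` counts: large enough that the low-carotenoid class
  has realistic structure and SNV has scatter to correct, small enough
  that band shape, not baseline, dominates class geometry.

The instrument axis is modelled as linear over 512 pixels even though the
optical resolution of such spectrometers (~8 cm^-1) exceeds the ~4.5
cm^-1 pixel spacing; band widths (12 cm^-1 nu1, 10 cm^-1 common bands)
are chosen so neighbouring nu1 positions overlap but remain separable.
The simulator does **not** model resonance-Raman cross-sections,
fluorescence photobleaching, skin/flesh layering, temperature effects or
pixel-to-pixel gain variation. Tests passing on these spectra therefore
demonstrate that the algorithms are implemented correctly and behave
sensibly under realistic noise — not that real fruit of any particular
panel will classify at the same rates.

## Pretreatments

SNV normalises each spectrum to zero mean and unit sample standard
deviation (denominator n-1) across the full range, removing the
multiplicative scatter factor. Savitzky-Golay filtering fits a
polynomial of order 2 (the chemometrics default; only window and
derivative order are conventionally reported) in a sliding odd window and
takes the derivative with respect to *index position*, matching
commercial chemometrics software. At the spectrum edges the full window
is fitted asymmetrically, so the number of variables never changes and
region-selection indices stay stable. The classification branch uses SNV
followed by a 25-point second derivative and the 1370-1700 cm^-1 region
(74 grid points on the default axis); the calibration branch uses a
15-point second derivative with smoothing. Mean centering is a fitted
step: column means are estimated on training data only and re-applied
unchanged to test data, inside every cross-validation fold as well, so no
test-set statistic ever leaks into a model.

The ordering SNV -> derivative follows the order in which the
pretreatments are conventionally listed; the reverse order is available
by building the plan the other way round and performed comparably in our
experiments. Region bounds are closed intervals.

## SIMCA

Each class gets an independent PCA model: class mean, `k` orthonormal
loadings, and a residual scale. The number of components per class is
chosen by leave-one-out cross-validated reconstruction error (PRESS),
capped at `min(n_c - 4, 10)`; the cap keeps enough residual degrees of
freedom in every leave-one-out submodel to estimate a scale at all.

Two residual scales are kept:

* `s0`, the classical fitted scale `sqrt(RSS / ((n_c - k - 1)(p - k)))`;
* `s0_cv`, the root mean of the leave-one-out residual variances, i.e.
  the scale of residuals of class members the model has *not* seen.

Derivative-filtered spectra have strongly correlated residuals, so the
classical F-test on `(p - k, (n_c - k - 1)(p - k))` degrees of freedom —
which assumes independent residual directions — is badly anticonservative
here: in our experiments it rejected the majority of genuine held-out
class members. The package therefore calibrates admission directly
against the cross-validated within-class residual distribution: each
class's held-out residual variances are standardised by the class's
`s0_cv^2`, pooled across classes (the shape of this distribution is
driven by the shared filtering, not by the class), and the pooled
`1 - alpha` quantile sets every class's admission cutoff. The parametric
F rule remains available (`admission = "f"`).

The default admission level is `alpha = 0.01`, matching the 0.99
chi-square level of the score-space Mahalanobis outlier rule, so both
"is this spectrum foreign to the class?" criteria operate at the same
strictness. A 5% admission test would, by construction, reject one in
twenty authentic fruit as belonging to no class; with external validation
sets of twenty-odd samples that alone caps expected accuracy near 95%
and makes reported accuracies mostly a measure of alpha rather than of
the spectroscopy. One-percent admission keeps the foreign-sample guard
while letting classification errors reflect actual class overlap.

Class assignment: a sample's F-ratio against each class is its residual
variance over that class's `s0_cv^2`; the prediction is the admitted
class with the smallest F-ratio, and a sample admitted nowhere is
deliberately counted as an error in accuracy reports. Standardising by
the cross-validated scale matters: with fitted scales, small or
heterogeneous classes (large unexplained variance) systematically absorb
their neighbours.

Interclass distance between classes a and b is
`sqrt((s_ab^2 + s_ba^2) / (s_aa^2 + s_bb^2)) - 1` built from pooled
residual standard deviations of each class's training samples under each
model; the `- 1` makes self-distance exactly zero, and values above 3
conventionally indicate well-separated classes. Discriminating power is
the per-variable version of the same ratio. Note that after a wide
second-derivative filter the discriminating wavenumbers are delocalised
across the filter window, so discriminating-power profiles are most
interpretable on normalised (underivatised) spectra; the package computes
them for whatever preprocessing the model was fitted with.

## PLS1 calibration

`pls1_fit()` is a NIPALS PLS1: weights from `X'y`, scores, loadings and
deflation, with the regression vector `b = W(P'W)^{-1}q` mapping centered
spectra to the centered response. Leave-one-out cross-validation refits
the centering and the full sequence of latent variables in every fold;
`SECV(a) = sqrt(sum(e^2)/n)` (divisor n, no bias correction — error
conventions differ between packages and the uncorrected root mean square
is the transparent choice), and the selected number of latent variables
is the global SECV minimum with ties resolved towards the smaller model.
External performance is summarised by the Pearson correlation and
`SEP = sqrt(mean(residual^2))` on a held-out split, stratified by
concentration quartile so both ends of the range appear in validation.
Residual outliers are flagged beyond 3 standardised residual sds.

## The multilayer perceptron

The network is implemented from first principles because the training
loop itself (backpropagation, inverted dropout, ADAM with bias
correction, early stopping with best-weight restoration) is part of what
this package demonstrates; its gradients are verified against central
finite differences in the test suite, which is the load-bearing
correctness check for the whole module.

Design choices where the application leaves room:

* He-uniform initialisation for ReLU layers; for regression the output
  bias starts at the training-response mean so the ReLU output unit is
  born active (a dead output unit would never recover under
  backpropagation).
* Full-batch training: the benchmark has ~100 samples, so batching adds
  variance without saving memory.
* ADAM at its recommended defaults (lr 0.001, beta1 0.9, beta2 0.999,
  eps 1e-8).
* Early stopping monitors validation loss with patience 50 (2000 epochs
  and patience 100 for the regression pipeline, which converges more
  slowly on mean-squared error); the best-validation weights are
  restored.
* Hyperparameter search samples uniformly: 1 or 2 hidden layers, 2-250
  neurons per layer, dropout 0-0.9 (a rate of 1 drops every unit and is
  excluded). Classification tables are ranked by test accuracy then test
  cross-entropy, mirroring how such searches are conventionally
  tabulated; regression models are ranked and chosen by *validation*
  loss, and the test split is touched only for the final report.
* Sliding-window variable selection (62 points, step 2, 226 candidate
  windows on the full axis) scores each window on the validation split
  with deliberately cheap evaluators — nearest-class-centroid error for
  classification, a 2-latent-variable PLS validation RMSE for
  regression — because the selection only needs to find the informative
  region, not the best model. Ties go to the leftmost window.

Classification inputs are mean-centered spectra only (no SNV or
derivative), which is the conventional minimal pretreatment for neural
networks on spectra; the nonlinearity is left to the network.

## The benchmark pipelines

`run_classification()` simulates 106 samples across the seven classes
(30/12/12/16/8/15/13 — red-fruit classes dominant, as in a typical
breeding panel), averages triplicates, and runs both classifiers: SIMCA
on a stratified 80/20 split and the MLP on a stratified 80/10/10 split
with a 50-trial search. It also reports the full-data interclass
distance matrix and the wavenumber of maximal discriminating power for
the pure-lycopene vs beta-carotene pair. `run_quantification()`
simulates 58 lycopene-dominant samples (concentrations uniform on
1.8-21.5 mg/100 g), calibrates PLS1 with LOO-CV on a stratified 80/20
split and the MLP regressor on a 60/20/20 split. A beta-carotene run at
its natural small n (17) is supported and flagged accordingly. All stage
seeds derive from the single config seed; reports are bit-reproducible.

These problem sizes keep a full benchmark run (both pipelines, including
the network searches) in the low minutes on one CPU.

## Numerical choices and degenerate inputs

* SNV refuses zero-variance spectra; discriminating-power denominators
  are floored at a relative epsilon to guard exactly-zero within-class
  residuals.
* NIPALS stops early when `X` is exhausted (weight norm below 1e-14);
  LOO folds that lose rank carry their last valid prediction forward.
* A class lying exactly in a k-dimensional subspace has `s0 = s0_cv = 0`;
  such a class admits exactly the spectra it reconstructs perfectly.
* Split sizes use largest-remainder rounding (per stratum when
  stratified), so 106 samples at 80/10/10 give 85/11/10-style splits
  with nothing lost or duplicated.
* Cross-entropy clips probabilities at 1e-12; softmax subtracts the row
  maximum before exponentiation.

## Known limitations

* The simulator's class geometry is simpler than real fruit: real
  within-class variation includes ripeness gradients, skin thickness and
  chlorophyll interference that no term here represents. Absolute
  accuracy figures on the benchmark characterise the pipeline under the
  stated noise model only.
* SIMCA admission calibration pools standardised residuals across
  classes; with very few classes or very small classes the pooled
  quantile is noisy, and the parametric option may behave differently.
* The MLP is CPU-bound, full-batch and two-hidden-layers-max by design;
  it is a faithful small-data workhorse, not a general deep-learning
  framework.
* Quantification accuracy is ultimately floored by the multiplicative
  scatter that survives replicate averaging (sd 0.15/sqrt(3) ~ 8.7% per
  averaged sample); no model, linear or not, can predict concentration
  below that noise floor from these spectra alone.
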