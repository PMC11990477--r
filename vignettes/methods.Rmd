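---
title: "Methods: OAV scoring, chemometrics and the synthetic data model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OAV scoring, chemometrics and the synthetic data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinosense)
```

This vignette documents the statistical methods implemented by
**vinosense**, the conventions and defaults chosen where the underlying
methods leave freedom, and the synthetic data model used to exercise the
pipeline when no instrument data are available.

## 1. Odor activity values and odorant series

The odor activity value of a volatile compound is the ratio of its
concentration to its odor perception threshold (OPT) in the matrix:

$$\mathrm{OAV} = \frac{c}{\mathrm{OPT}}$$

`compute_oav()` enforces OPT > 0 and matching units. A compound is flagged
*aroma-active* when OAV strictly exceeds the activity threshold
(default 0.2); the inequality is strict, so a compound sitting exactly at
the threshold is not flagged.

Compounds are grouped into eleven odorant series (chemical, fruity/ripe
fruit, green fruit, green, floral, creamy, citrus, herbaceous,
toasty/smoky, honey, waxy). A series score for a sample is the **sum of
the OAVs of its member compounds**; a compound assigned to several series
contributes its full OAV to each of them. Consequently series scores are
additive over any partition of the compound list, scale equivariantly with
the OAV matrix, and their row totals equal the multiplicity-weighted OAV
sums — all of which the test suite verifies.

The package ships a 57-compound, five-wine OAV dataset
(`load_fivewine_fixture()`), with wines fermented by spontaneous flora
(WY), *S. cerevisiae* (SC), *M. pulcherrima* (MP), and
*L. thermotolerans* free (LT) or immobilised in biocapsules (BC), plus a
matching synthetic-threshold map for exercising the concentration→OAV
path.

## 2. Scaling, PCA

`autoscale_fit()` centres each column and divides by its SD (denominator
$n-1$); zero-variance columns are an error in autoscale mode, named in
the message. `pca_fit()` wraps `stats::prcomp()` (SVD) and adds a
deterministic sign convention: each component is flipped so that its
largest-magnitude loading entry is positive. Explained-variance fractions
are $\lambda_i / \sum_j \lambda_j$ over **all** eigenvalues, so they sum
to 1 only at full rank.

## 3. NIPALS PLS2, PLS-DA and VIP

`pls2_fit()` implements the NIPALS algorithm with deflation of both
blocks. Per latent variable: the starting $\mathbf{u}$ is the largest-SS
column of the (deflated) $\mathbf{Y}$; iterate
$\mathbf{w} \propto \mathbf{X}'\mathbf{u}$ (unit norm),
$\mathbf{t} = \mathbf{Xw}$, $\mathbf{q} = \mathbf{Y}'\mathbf{t}/\mathbf{t}'\mathbf{t}$,
$\mathbf{u} = \mathbf{Yq}/\mathbf{q}'\mathbf{q}$ until the score vector
changes by less than `tol = 1e-10` (relative), up to
`max_iter = 5000` iterations — non-convergence is a classed error naming
the LV. The loading is $\mathbf{p} = \mathbf{X}'\mathbf{t}/\mathbf{t}'\mathbf{t}$
(sign-fixed like PCA components) and both blocks are deflated by the
rank-one fit. Per-LV explained variance of each block is the deflated
sum-of-squares fraction. The coefficient matrix is
$\mathbf{B} = \mathbf{W}(\mathbf{P}'\mathbf{W})^{-1}\mathbf{Q}'$.

`plsda_fit()` one-hot encodes the class labels (level order = first
appearance), centres the responses, auto-scales $\mathbf{X}$ and fits
PLS2; `plsda_predict()` assigns the class with the largest predicted
response, breaking exact ties toward the lowest class index with a
warning. Variable importance in projection is

$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_a \mathrm{SSY}_a w_{ja}^2}
{\sum_a \mathrm{SSY}_a}},$$

which satisfies $\mathrm{mean}(\mathrm{VIP}^2) = 1$ for every fitted
model; sensors with VIP > 1 are conventionally called influential.

## 4. Cross-validation, PCR and figures of merit

`venetian_folds(n, s, w)` builds venetian-blind folds: with thickness
$w = 1$, fold $i$ contains samples $i, i+s, i+2s, \dots$ (interleaved
partition); general thickness groups $w$ consecutive samples per blind.
Splits default to $\min(n, 10)$.

`pcr_fit()` auto-scales $\mathbf{X}$, extracts $k$ principal components
and regresses the centred responses on the scores by least squares
(`qr.solve`). Per response, `regression_metrics()` reports the reference
mean/min/max/SD ($n-1$), plus

- $\mathrm{RMSEC} = \sqrt{\tfrac{1}{n}\sum (y - \hat y_{\mathrm{cal}})^2}$,
  and RMSECV likewise from venetian-blind CV predictions,
- $R^2 = 1 - \mathrm{PRESS}/\mathrm{SS}_{\mathrm{tot}}$ for calibration
  and CV,
- $\mathrm{RPD} = \mathrm{SD}/\mathrm{RMSECV}$ (an exact identity of the
  emitted table, validated before writing).

When a component count is not supplied, `select_components()` takes the
first local minimum of the RMSECV curve (falling back to the global
minimum with a warning when the curve is monotone); the
`replicate_paper = TRUE` profile pins 3 PLS-DA latent variables, 5 PCR
components and blind thickness 1 instead. `pearson_map()` returns the
11 × 12 Pearson correlation matrix between series scores and sensor
responses (NA for zero-variance columns, $n \ge 3$ required).

The prediction stage treats sensor responses as predictors of the series
scores (the calibration direction of practical interest — inferring aroma
character from the instrument); `run_prediction(reverse = TRUE)` swaps
the blocks.

## 5. The synthetic data model

No replicate-level instrument data are published for this kind of study,
so the generator (`sim_config()`, `generate_dataset()`) produces
class-structured data with a known ground truth:

- **Profiles.** Each of the five wine classes has a true 11-series
  profile (default: the per-wine series scores of the packaged dataset).
  An observed replicate is $m_{kj}(1 + \delta)$ with
  $\delta \sim N(0, \mathrm{cv}^2)$, truncated at 0. The default
  `cv = 0.08` reflects typical analytical repeatability of quantified
  volatiles. Default design: 5 classes × 6 replicates.
- **Sensors.** A 12-sensor quartz-microbalance array responds linearly:
  $\Delta f = \text{profile} \cdot K + b + \varepsilon$, with
  $\varepsilon \sim N(0, \sigma^2)$ and `sigma = 1` Hz (a realistic QMB
  noise floor). The default sensitivity matrix $K$ is strictly negative
  (mass adsorption lowers the resonant frequency), full rank, and its
  magnitudes span about 2.5 decades — sensor films differ in affinity by
  orders of magnitude, and this spread keeps the 12 channels from being
  near-collinear.
- **Seeding.** Profile noise uses `seed`; sensor noise uses `seed + 1`,
  so the same profiles can be re-paired with fresh sensor noise. The
  caller's RNG state is saved and restored.

What the model does emulate: class separation, multiplicative
concentration noise, additive sensor noise, a linear response surface,
and exact reproducibility. What it does not: sensor drift dynamics,
nonlinear adsorption isotherms, humidity/temperature effects, or
compound-level (rather than series-level) sensor selectivity. No
headline number may therefore depend on the synthetic scales — they are
configurable, and the acceptance checks on synthetic data are structural
(perfect recovery without noise, degradation with noise, calibration
optimism) rather than numeric.

```{r example, eval = FALSE}
cfg <- run_config(synthetic = TRUE, sim = sim_config(seed = 1),
                  seed = 1, replicate_paper = TRUE, out_dir = "results")
res <- run_all(cfg)
res$prediction$metrics
```

## 6. Conventions adopted where sources are ambiguous

- Frequency shifts are kept **signed** (negative for adsorption);
  `steady_state_shift()` is the response-window mean minus the
  baseline-window mean, with no absolute value.
- The aroma-active count is always recomputed from the OAV matrix by
  brute force, never hard-coded, since printed summary counts can lag
  the underlying table.
- The classification stage errors when any class has fewer than two
  samples (cross-validation and SDs are undefined), with guidance to add
  replicates or merge classes.
- NIPALS `max_iter` defaults to 5000: noise-dominated CV folds can have
  tiny eigengaps, and 500 iterations were observed to be insufficient
  there while 5000 costs microseconds.
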