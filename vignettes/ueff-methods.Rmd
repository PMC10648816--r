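---
title: "Calibrating an ultrasound-estimated fat fraction: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating an ultrasound-estimated fat fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ueff)
```

## The problem

Hepatic steatosis is routinely quantified by the MRI proton density fat
fraction (MRI-PDFF, in percent), but MRI is expensive and not always
available. Two quantitative ultrasound (QUS) parameters track liver fat:
the attenuation coefficient (AC, dB/cm/MHz), which measures how quickly
the ultrasound beam loses energy in tissue, and the backscatter-distribution
coefficient (BSC-D, arbitrary units), a statistic of the echo-amplitude
distribution. Both increase with fat content and both saturate as the fat
fraction rises — BSC-D more strongly than AC — so a linear map from either
parameter to MRI-PDFF is misspecified at the upper end. This package
calibrates a non-linear map, the ultrasound-estimated fat fraction (UEFF),
and quantifies how well it reproduces and classifies MRI-PDFF.

## Measurement-level quality control

A clinical QUS session yields repeated readings per patient, each with a
validity metric. `aggregate_measurements()` encodes the acquisition rules:

* **TAI** (AC): readings with regression fit R² < 0.6 are discarded; at
  least 5 valid readings must remain; their arithmetic mean is the
  patient's AC. If more than five valid readings exist, all are used.
* **TSI** (BSC-D): no per-reading metric exists; at least 5 readings are
  averaged.
* **SWE** (liver stiffness, kPa): readings with reliable measure index
  (RMI) < 0.4 are discarded; at least 5 must remain *and* their
  IQR/median ratio must be below 0.30, otherwise the session is rejected
  as too dispersed.

Two conventions had to be fixed because the acquisition rules do not state
them. Quartiles for the IQR/median rule use linear interpolation between
order statistics (`quantile()` type 7, R's default), so the 0.30 cut is
reproducible. And "at least five valid measurements" is interpreted as a
*post hoc* filter — the aggregator never asks whether invalid readings
were re-acquired, it only checks what survives.

## The calibration model

Each single-predictor model is the three-coefficient exponential

$$\widehat{\mathrm{PDFF}} = \beta_1 e^{\beta_2 x} + \beta_3, \qquad
x \in \{\mathrm{AC}, \mathrm{BSCD}\},$$

fitted by Levenberg–Marquardt least squares. For $\beta_1 > 0,
\beta_2 > 0$ the curve is strictly increasing and convex in the predictor,
which is the saturation story seen from the other axis: equal increments of
fat produce ever smaller increments of the ultrasound parameter.

The combined model is additive with a shared offset,

$$\widehat{\mathrm{PDFF}} = \beta_1 e^{\beta_2 \cdot \mathrm{AC}}
  + \beta_3 e^{\beta_4 \cdot \mathrm{BSCD}} + \beta_5,$$

five free coefficients in all. The form was a genuine design choice: an
additive two-exponential keeps each predictor's marginal response equal to
the single-predictor law, counts more trainable coefficients than either
single model (which is the textbook overfitting risk for a combined
model), and nests the AC-only model (set $\beta_3 = 0$), so on any
training set its SSE can never be worse — a property the test suite checks
numerically. Alternatives (multiplicative coupling, a shared rate) would
have broken either the marginal-shape property or the nesting.

### Numerical choices

* **Start values** are deterministic and documented: $\beta_3$ starts at
  $\min(y)$; an ordinary least-squares line through
  $\log(y - \beta_3 + \varepsilon)$ on $x$ supplies $\beta_2$ (slope) and
  $\beta_1$ (exponentiated intercept), with
  $\varepsilon = 10^{-6} + 0.001\,\mathrm{range}(y)$ guarding the log.
  The combined fit chains this heuristic: AC-only first, then its
  residuals seed the BSC-D term.
* **Internal standardisation.** The optimiser works on
  $z = (x - \bar{x})/s_x$ and maps coefficients back exactly
  ($\beta_2 = \beta_2'/s_x$, $\beta_1 = \beta_1' e^{-\beta_2'\bar x/s_x}$).
  This is a pure reparameterisation — the SSE surface is unchanged — but
  it conditions the Jacobian when predictor scales are far from 1 (BSC-D
  lives near 100), which matters because the combined model has a weakly
  identified direction (see limitations).
* **Convergence** is declared at a relative SSE change below `1e-10`
  within 500 iterations; both limits, the iteration count, the final SSE
  and the start values are stored in `fit_meta`. A fit that exhausts the
  caps raises a classed error rather than returning silently.
* **Degenerate inputs**: a constant predictor makes the rate
  unidentifiable and is refused; near-collinear predictor pairs
  (|r| > 0.999) are fitted but flagged in `fit_meta$collinear` and as a
  warning. Residuals that overflow to non-finite values during a trial
  step are capped so the step is rejected instead of corrupting the
  optimiser state.
* **Predictions are never clipped.** A slightly negative UEFF for a very
  lean liver is a legitimate output of the affine-plus-exponential form,
  and clipping would bias downstream correlation and ROC analyses.

Goodness of fit is summarised by $R^2 = 1 - SS_{res}/SS_{tot}$, the
adjusted $R^2 = 1 - (1 - R^2)(n-1)/(n-p-1)$, and the RMSE in percent
PDFF. `p` counts *ultrasound predictors* (1 or 2), not raw coefficients:
the adjustment is for independent variables, and this keeps single and
combined models comparable on the same penalty scale. On external data
both $R^2$ values may be negative and are returned unclamped.

## Validation design

`repeated_kfold_cv()` uses plain (non-stratified) random partitions:
per repeat a seeded shuffle deals records into k folds whose sizes differ
by at most one; each fold serves once as the validation set for a model
refitted from scratch on the rest. The default scheme, 3 folds × 5
repeats, yields 15 held-out evaluations summarised as mean ± sample SD
(n − 1 denominator). Stratification by steatosis grade was deliberately
not added — with n = 90 and four grades the plain scheme keeps folds
exchangeable and the code simpler; the cost is slightly noisier fold
compositions. A fold whose refit fails to converge is excluded from the
aggregate, counted, and reported by warning — never silently dropped.

`external_test()` applies a frozen model to an independent cohort — the
design that mimics calibrating on one disease group (NAFLD-like) and
deploying on another (MAFLD-like). Disjointness is the caller's
responsibility and is documented through cohort provenance rather than
enforced, since the two cohorts may legitimately share nothing but a
column schema.

## Statistical machinery

* **Correlations** use Fisher's z: the 95% CI is
  $\tanh(\mathrm{atanh}\,\rho \pm z_{0.975}/\sqrt{n-3})$, the p-value the
  t-transform on n − 2 df. This closed form reproduces published
  correlation intervals of this workflow to their printed precision, which
  is why no bootstrap alternative was considered. Perfect correlations
  degenerate to the interval $(\rho, \rho)$ by convention.
* **The sub-range scan** (`subrange_correlation_scan()`) addresses where
  saturation erodes the UEFF–PDFF agreement: it exhaustively evaluates
  every contiguous PDFF interval whose endpoints are observed values and
  which retains at least half the records (configurable), returning the
  interval with maximal Pearson correlation; ties go to the widest
  interval so exactly linear data return the full range. How the
  "strongest" sub-range was located in the original workflow is not
  documented anywhere; an exhaustive scan is the transparent
  interpretation, and its output is labelled exploratory — the maximal
  correlation over many overlapping windows is upward-biased by selection.
* **Group comparisons** use the tie-corrected Kruskal–Wallis H
  (via `kruskal.test`) with Dunn z-tests on mean ranks, tie-corrected
  pooled variance, two-sided p-values and Holm step-down adjustment over
  all pairs. An all-equal sample is reported as H = 0, p = 1 by
  convention rather than NaN.
* **ROC analysis** computes the AUC by the Mann–Whitney identity (tied
  pairs count ½) and its CI from DeLong's placement variance, clipped to
  [0, 1]. The Youden-optimal cutoff maximises J = sensitivity +
  specificity − 1 over midpoints of adjacent distinct scores plus ±∞,
  with ties broken toward the higher cutoff (higher specificity); the rule
  `score ≥ cutoff` is positive. One source formulation defines J as
  "true positive rate − false negative rate", which equals 2·TPR − 1 and
  ignores specificity entirely; it cannot produce cutoffs that trade
  sensitivity against specificity, so it is read as a slip for the
  standard Youden index. The literal formula remains available
  (`j_definition = "literal"`) for auditability.
* **Power** for each binary task is the approximate power of the
  two-sided z-test of AUC = 0.5, using Hanley–McNeil variances evaluated
  at the null and at the observed AUC. The CI and power methods are
  documented assumptions — the workflow this package implements names
  neither.

## What the synthetic generator does and does not emulate

No patient-level data ship with the package; `generate_cohort()` creates
cohorts with the statistical structure the analysis relies on:

* a four-grade steatosis mix (defaults: 0.211/0.244/0.378/0.167 for the
  NAFLD-like group, 0.549/0.157/0.196/0.098 for the MAFLD-like group),
  converted to exact counts by largest-remainder rounding so counts always
  sum to n;
* a latent fat fraction drawn uniformly within each grade band
  (<5, 5–10, 10–20, ≥20%, the last truncated at 45% by default);
* AC obtained by *inverting* the exponential link on the latent fat
  fraction, so the calibration model is correctly specified by
  construction and noiseless cohorts identify the link coefficients
  exactly (the test suite requires recovery to 1e-6 relative error);
* observed MRI-PDFF = latent fat + Gaussian noise (SD 6.4% by default),
  clipped to [0, 100];
* BSC-D from a saturating response `c1 + c2(1 − exp(−c3·PDFF))` plus
  noise — saturation in the *BSC-D* direction is built in as the stronger
  of the two, matching the qualitative behaviour of backscatter
  statistics;
* liver stiffness log-normal and *independent* of fat (the analysis
  treats stiffness as a non-predictor, and the generator encodes that
  null);
* BMI as a normal baseline plus an effect proportional to log1p(PDFF).

Default link coefficients (AC: 5.447, 1.974, −15.93; BSC-D: 80, 36.75,
0.0677), noise SDs and marginal distributions are package fixtures
calibrated once by least squares against the published marginal summaries
of the two study groups (AC 0.83 ± 0.15 over 0.55–1.22 dB/cm/MHz, BSC-D
100.5 ± 9.6, LS 7.24 ± 3.2 kPa, MRI-PDFF 12.1 ± 8.86% for the discovery
group); the PDFF noise SD was set to reproduce the reported
cross-validated RMSE of about 6.4%. They are modelling choices, not
measured constants. One master seed spawns per-variable substreams, so
changing one variable's parameters does not shift another's draws and
cohorts are bit-reproducible.

What the generator does **not** emulate: joint dependence beyond the
links above (no fibrosis–fat coupling, no covariate-dependent measurement
error), heavy-tailed or skewed measurement noise, scanner/operator batch
effects, or any real acquisition physics. Consequently, passing tests
demonstrate that the *pipeline* is correct under its own assumptions —
they say nothing about how a particular scanner's AC maps to fat in
patients.

## Sizes, seeds and tolerances used by the checks

The test suite and acceptance script run entirely on generated data at the
study's scale: discovery cohorts of n = 90, external cohorts of n = 51,
3 × 5 cross-validation, 100-cohort coefficient-recovery batches, 200
random ROC instances against a brute-force pair-counting oracle, and 2000
binormal simulations for DeLong coverage — the last chosen so the
Monte-Carlo standard error (≈0.5%) is small against the ±2% band being
verified. Exact-recovery assertions use 1e-6 relative tolerance
(noiseless identifiability), oracle-equivalence assertions 1e-10 to
1e-6 depending on the arithmetic involved, and all simulation-based
assertions run under fixed seeds recorded in the tests themselves.

## Known limitations

* **The combined model is weakly identified.** When BSC-D adds little
  beyond AC, the surface along ($\beta_3, \beta_4$) flattens: $\beta_3$
  grows while $\beta_4 \to 0$, their product's first-order term absorbing
  the offset. Fits remain excellent predictors, but these coefficients can
  take extreme, mutually compensating values, and an occasional
  cross-validation fold exhausts the iteration cap and is excluded (with a
  warning). This mirrors the instability a combined model shows in
  practice.
* **Coefficient recovery under realistic noise is poor even when
  prediction is good.** With the default noise (SD 6.4% PDFF) the
  three-coefficient exponential's SSE valley is flat along correlated
  coefficient directions; median relative coefficient errors over
  100 cohorts of n = 90 are roughly 0.25–0.6 per coefficient, an order of
  magnitude above what noiseless data achieve. Reporting UEFF predictions
  is robust; interpreting individual fitted coefficients is not.
* The sub-range scan's maximal correlation is selection-biased upward and
  should be read descriptively.
* The generator's uniform-within-band fat distribution slightly
  over-disperses the upper grade relative to a clinical cohort with the
  same grade mix; summary SDs run a little high as a consequence.
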