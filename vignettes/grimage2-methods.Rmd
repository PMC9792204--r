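---
title: "Methods: two-stage DNAm mortality clocks and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage DNAm mortality clocks and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grimage2)
```

## The model

GrimAge-style mortality clocks rest on two empirical facts: some plasma
protein levels can be estimated from blood CpG methylation, and those
estimated ("DNAm surrogate") levels predict all-cause mortality better than
the assayed proteins themselves. The package implements both training
stages and everything needed to validate the result on new cohorts.

**Stage 1.** For an analyte $y$ (CRP in mg/L, A1C in %), the training
target is $\log w(y)$, where $w$ winsorizes the raw values: observations
whose z-scores exceed 6 are replaced by the largest observation with
z-score $\le 6$. Winsorization is upper-tail only — both analytes are
right-skewed, and the quoted-scale rule only bites on the right; the
observed minimum is stored as a lower clamp for prediction-time safety. The
surrogate is the elastic-net fit of this target on all CpG beta values plus
age and sex (all penalized candidates alike),

$$\hat\beta = \arg\min_\beta \tfrac{1}{2n}\lVert y - X\beta\rVert^2
 + \lambda\left(\alpha\lVert\beta\rVert_1 +
   \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right),$$

with predictors standardized internally and coefficients reported on the
original scale. One unit of the *scaled* surrogate
(`scale_surrogate()`) is one training-sample SD of the surrogate.

**Stage 2.** The mortality clock minimizes the penalized negative log
partial likelihood (Breslow ties) of time-to-death on the DNAm surrogates,
age and sex. The linear predictor $X^\top\beta$ is a log relative hazard;
`calibrate_to_age()` maps it affinely so its training mean and variance
equal those of chronological age, giving an estimate in years. This
calibration is exact by construction — the training mean/SD of the
calibrated clock equal the age mean/SD to floating-point precision — which
is what the packaged published transform ($-61.03936 + 8.271105\,X^\top\beta$)
encodes for its own training cohort.

**Derived scores.** Age acceleration is the OLS residual of a DNAm measure
on chronological age: positive values mean epigenetically older than
expected. `mortality_res()` computes deviance residuals from a *fixed*
linear predictor: the Breslow cumulative baseline hazard
$\hat\Lambda_0$ is estimated from the data with risk scores $e^{lp}$,
martingale residuals $m_i = \delta_i - \hat\Lambda_0(t_i)e^{lp_i}$ sum to
zero, and $d_i = \mathrm{sign}(m_i)\sqrt{-2[m_i + \delta_i\log(\delta_i - m_i)]}$.
This differs from `residuals()` on a fitted `coxph` only in that the linear
predictor is supplied, so a clock trained elsewhere can be scored on a test
cohort; with an all-censored cohort the baseline hazard is identically zero
and a zero vector is returned with a warning.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `alpha` | 0.5 | — | Midpoint of ridge/lasso, the convention in methylation-clock work; the mix is rarely critical and is user-settable. |
| `n_folds` | 10 | — | Standard CV fold count for both stages. |
| `lambda` | CV minimum | — | Chosen at the minimum of cross-validated error (gaussian MSE in Stage 1, partial-likelihood deviance in Stage 2), not the one-SE rule: the goal is predictive surrogates, not sparse interpretation. |
| `seed` | 1 | — | Drives the single random fold shuffle; two fits with the same spec are bit-identical. |
| winsor `z_max` | 6 | SD | The scaled-value threshold defining raw-scale analyte outliers. |
| masking threshold | 6 | SD | Per-CpG EWAS outlier masking, one pass with moments from the unmasked input. |
| `bicor` `c` | 9 | MAD | Tukey biweight tuning constant; observations beyond 9 unscaled MADs from the median get zero weight. |

Fold assignment shuffles samples once with the stated seed into near-equal
folds, without outcome stratification.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the two stages
assume, at the training-cohort scale the clock was designed for: default
n = 1833, 1030 CpGs, ages with empirical mean 66.1 and SD 9.06 years
(affine standardization makes the moments exact), ~50% female, zero-inflated
smoking pack-years, and a Weibull-baseline (shape 1.5, so the hazard rises
with time) proportional-hazards mortality process with uniform independent
censoring tuned to ~13% deaths. Each analyte loads on its own disjoint set
of 20 causal CpGs through a per-sample latent factor; the analyte equals
that CpG-linear signal plus small age/sex effects plus Gaussian noise sized
so the recoverable signal explains 80% of the variance ($R^2 = 0.8$, a
deliberately favorable but not trivial signal-to-noise ratio). The
CRP-like analyte is exponentiated to produce the right skew that makes the
winsorize-then-log pipeline meaningful.

What the generator does *not* emulate: array batch effects, pedigree and
repeated-measure correlation, cell-composition confounding, age-analyte
interactions, and the heavy-tailed measurement error of immunoassays.
Passing recovery tests therefore show the estimators are correct under
their own assumptions — not that real-cohort effect sizes will match.

Simulated effect sizes for recovery tests were chosen once for statistical
power: with two Cox covariates at n = 2000 and ~40% events, true log
hazard ratios of (1, −0.8) put a 15% relative-error band at roughly three
sampling SDs, so recovery checks measure correctness rather than
Monte-Carlo luck.

## Numerical choices and degenerate inputs

- Elastic-net solutions come from coordinate descent (`glmnet`) with a
  tight convergence threshold (`1e-12`) where exact limits are compared
  (the unpenalized limit matches normal equations / Newton partial
  likelihood to 1e-6 / 1e-4).
- Winsorization with zero-SD input returns the vector unchanged with
  `lo = hi`; full-shrinkage surrogates (constant predictions) store unit
  `train_sd` so scaling stays defined.
- Missing data: Stage-1 fitting drops samples listwise per target;
  applying a surrogate imputes missing betas from stored per-CpG training
  means when available, otherwise errors. Matrix values outside [0, 1] are
  rejected at read time; a first file column that looks like CpG IDs
  triggers a "transposed input" error.
- `bicor` falls back from a zero MAD (majority tied at the median) to the
  SD with a warning; correlations are clamped to [−1, 1] against rounding.
- Calibration uses sample SDs (n − 1); the age supplied to
  `calibrate_to_age()` is taken as *the* age variable (cohorts that average
  ages across exams should do so before calling).
- Meta-analysis of correlations pools on the Fisher-z scale with variance
  1/(n − 3) and back-transforms the pooled estimate — the
  variance-stabilized choice; pooling raw correlations would bias toward
  strata with large |r|.
- Two-sided p-values throughout; normal reference for meta statistics,
  Student-t for per-CpG correlation screens. No multiple-testing
  adjustment by default (reported P is unadjusted); `ewas_numeric_trait()`
  offers Bonferroni/BH columns.

## Design decisions made where the design was open

- **Left truncation.** Follow-up measured from an earlier exam implies
  delayed entry; the package fits standard right-censored Cox models and
  documents the simplification rather than guessing an entry-time scheme.
- **Pedigree/repeated-measure correlation** is handled by cluster-robust
  (Huber sandwich) standard errors keyed on a cluster column, replacing
  mixed-model and GEE variants; point estimates are unchanged and the
  robust variance is the defensible, always-convergent alternative.
- **Stage-2 CV criterion** is partial-likelihood deviance (not C-index):
  it is the likelihood-scale analogue of the Stage-1 criterion and is
  convex in the linear predictor.
- **EWAS screening statistic** is the per-CpG Pearson correlation with a
  Student-t p (numeric traits) or a per-CpG Cox Wald test (censored
  traits), after six-SD masking.
- **Extreme-value masking is one-pass**: moments come from the unmasked
  input and are not recomputed, so a gross outlier can shield a smaller
  one within the same pass. Iterating would change the rule's semantics.

## Problem sizes used by the test suite

Unit tests run at n = 60–500 with 12–150 CpGs; cohort-scale checks use
n = 1833–2500 with 200–500 CpGs (the surrogate out-of-sample recovery and
the calibration identity), 1000 null CpGs for EWAS calibration, and 50
replicates for Cox type-I coverage. These sizes were chosen so each check
has clear statistical resolution while the full suite stays quick to run.

## Known limitations

- The per-CpG weights of the ten published DNAm components were never
  released; `grimage2_model()` therefore operates at the surrogate level
  and users must supply component values (from the clock provider or from
  surrogates trained with this package on their own data).
- Exact replication of the published CpG counts per surrogate (132 for
  logCRP, 86 for logA1C) is not expected: the mixing parameter, penalty
  grid and fold seeds behind them were not published.
- IDAT processing and normalization (Noob/BMIQ/SeSAMe) are upstream of
  this package; it consumes finished beta matrices.
- Blood-cell composition estimates are accepted as plain covariate
  columns, not imputed from methylation.
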