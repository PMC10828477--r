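---
title: "Comparing DNA methylation ageing rates across tissues with methylRate"
author: "methylRate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing DNA methylation ageing rates across tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylRate)
```

# The question and the method

Epigenetic clocks — sparse linear models that predict chronological age from
CpG methylation beta values — are routinely used to ask whether one tissue
"ages faster" than another. Comparing raw DNAm ages across tissues is
treacherous, because a clock trained without adequate representation of a
tissue systematically mis-estimates it for reasons that have nothing to do
with ageing biology. `methylRate` implements a more symmetric design for a
pair of tissues measured on the *same* subjects:

1. **Paired-tissue age EWAS.** For each CpG $i$ and each tissue, ordinary
   least squares of the beta value on age and nuisance covariates,
   $\beta_i \sim w_{1i}\,\mathrm{Age} + w_{2i}\,\mathrm{Sex} +
   w_{3i}\,\mathrm{Batch} + w_{4i}\,\mathrm{Disease} + c_0$,
   with a two-sided Student's *t* test on $w_{1i}$ and Bonferroni control.
   A CpG is age-associated when its adjusted p-value is at most 0.01.
2. **Shared-CpG selection.** The intersection of the two tissues'
   significant sets — CpGs whose methylation tracks age in *both* tissues —
   is the only fair common currency for a rate comparison.
3. **Symmetric clock construction.** An elastic-net clock is trained on each
   tissue restricted to the shared set, minimizing
   $\tfrac{1}{2n}\sum_i w_i\,(y_i - c_0 - x_i^{\top}c)^2 +
   \lambda\sum_j \gamma_j\!\left[\tfrac{1-\alpha}{2}c_j^2 +
   \alpha\lvert c_j\rvert\right]$,
   with $\lambda$ chosen by internal cross-validation.
4. **Reciprocal application and slope reading.** Each clock is applied to
   the *other* tissue and the DNAm age is regressed on chronological age.
   If the A-trained clock yields a slope above 1 on tissue B while the
   B-trained clock yields a slope below 1 on tissue A, the two oppositely
   directed analyses agree that tissue A's shared CpGs change more slowly
   per year — tissue A has the smaller ageing tick rate on those CpGs.

Prediction quality is summarized by
$\mathrm{RMSD} = \sqrt{\tfrac{1}{m}\sum_i (y_i-\hat y_i)^2}$ and
$\mathrm{MAD} = \tfrac{1}{m}\sum_i \lvert y_i-\hat y_i\rvert$, the Pearson
correlation, and the slope/intercept of $\hat y$ on $y$. Age acceleration is
available both as the classical difference $\hat y - y$ and as the residual
from regressing $\hat y$ on $y$; the residual form is the default for
cross-tissue comparisons because it removes calibration-slope artefacts.

## Why the slope is the right read-out

Under a linear generative model the slope has a closed-form interpretation.
Suppose a shared CpG drifts as $\beta = b + w_A\,a$ in tissue A and
$\beta = b + k\,w_A\,a$ in tissue B. A clock calibrated to return age on
tissue A computes, on tissue B,
$\hat y(a) = c_0 + \textstyle\sum_j c_j (b_j + k w_{A j} a) \approx
\text{const} + k\,a$: the cross-applied slope *is* the effect-size ratio
$k$, and the reverse direction gives $1/k$. A pure baseline offset between
tissues ($b_A = b_B - \delta$ with equal slopes) moves only the intercept.
This analytic oracle is exercised directly by the test suite (slopes
$2$ and $0.5$ recovered for $k = 2$; both slopes $\approx 1$ for $k = 1$
with intercepts displaced in opposite directions under a baseline deficit).
The oracle holds for the identity age transform; with a log transform the
slope is bent by the link, so log-transform runs are interpreted
qualitatively (direction only).

# The synthetic cohort generator

Real paired-tissue methylomes with known ageing rates do not exist, so the
package ships a generator whose defaults emulate the cohort structure this
design targets; every setting is overridable through
`simulationConfig()`.

* **Subjects.** 404 subjects measured in both tissues; ages truncated-normal
  with mean 80 and sd 10 on [15, 114] — an elderly-skewed postmortem brain
  cohort. Six dataset batches with unequal sizes proportional to
  404:111:95:66:44:32, sex close to balanced, and a disease label on about
  56% of subjects (by default the disease has no methylation effect; a
  designated null-CpG subset can carry an additive shift to exercise the
  covariate adjustment).
* **CpG classes.** 201 CpGs age-associated in both tissues, 412 tissue-A-only,
  4012 tissue-B-only, 5000 null, and 200 sex-linked probes on chrX. The
  shared class is 94% methylation-gaining and drawn 70% from islands and
  24% from shores; other classes follow an array-like category mix.
* **Effects and baselines.** Per-year slopes are uniform in magnitude on
  [5e-4, 2.5e-3] beta/year (the order of magnitude of strong age-associated
  CpGs); tissue-B shared slopes are exactly $k$ times tissue-A's ($k = 2$ by
  default, i.e. tissue A changes at half the rate). Baselines are drawn per
  genomic category, with islands low, open sea high, and a 0.05 island/shore
  deficit in tissue A. Baselines are nudged per tissue into the feasible
  band so the linear trend does not systematically clip at 0/1 — slopes are
  never altered, keeping ratio oracles exact; a run that still clips more
  than 5% of values warns.
* **Noise model.** Additive Gaussian noise on the beta scale (sd 0.02 by
  default), clipped to [0, 1] — chosen for the analytic tractability of the
  slope-recovery oracles; per-CpG dataset-level batch offsets (sd 0.01)
  drawn once per run mimic plate/chip structure without modelling chips.
  Sex-linked probes are bimodal by sex (intermediate betas for females,
  extreme for males), an X-inactivation surrogate that exercises the sex
  estimator.

What the generator does *not* emulate: probe-level chemistry and design-type
intensity biases, cell-type composition and its age drift, nonlinear
methylation trajectories, and spatial correlation between neighbouring CpGs.
Tests passing on this generator therefore demonstrate that the pipeline's
statistics behave as designed under its stated model, not that the model
captures every property of array data.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| EWAS significance threshold | adjusted p ≤ 0.01 | Bonferroni-corrected cutoff for "age-associated" |
| EWAS covariates | sex, dataset, disease | dummy-coded, first observed level as reference |
| `alpha` (tissue-specific clock) | 0.5 | L1/L2 mix when training on a tissue's own significant CpGs |
| `alpha` (shared-CpG clocks) | 0.2 | lower values keep more of the small shared panel in the model |
| `lambda` | `"cv"` | MSE-minimizing value over seeded folds (`"1se"` rule available) |
| CV folds | 10 | internal lambda selection; clamped to the training size |
| age transform | `log1p` (training), identity for rate reads | `horvath` provided for interoperability |
| QC density threshold | 0.5 | max fraction of autosomal betas in [0.25, 0.75] |
| acceleration mode | residual | difference mode retained for the classical definition |

# Numerical choices

* **Elastic-net solver.** Cyclic coordinate descent with covariance updates
  on the standardized Gram matrix, warm starts along a geometric lambda
  path, and active-set inner iterations. The path is truncated once the
  deviance ratio saturates (R² > 0.999 or a per-step gain below 1e-5 of
  R²), because the flat small-lambda tail is where cross-validation cannot
  discriminate and where coordinate descent is slowest on the strongly
  correlated predictors a shared-CpG panel produces. Path and fold fits run
  at a light tolerance (1e-5 relative to sd(y), per-sweep coefficient
  change); the chosen lambda is then polished to 1e-10 from a warm start,
  so reported solutions satisfy the KKT stationarity conditions to ~1e-12
  on test fixtures while a full clock training stays around a second. The
  sweep order is fixed cyclic — deterministic by construction, so no
  randomness needs to be spent on it; folds and simulations draw their
  seeds from the single run seed.
* **Ridge-part convention.** The objective is the standard
  $\lambda[(1-\alpha)c^2/2 + \alpha|c|]$ per unit penalty factor on the
  standardized scale. glmnet divides its effective ridge term by sd(y)
  because it standardizes the response internally; the test suite
  cross-checks against glmnet after absorbing that rescaling into
  $(\lambda, \alpha)$, and exactly at $\alpha = 1$ where the conventions
  coincide.
* **Degenerate inputs.** Constant predictors get a coefficient of exactly
  zero; a constant response yields an intercept-only model; an EWAS CpG
  with residual sd below 1e-10 (an exact linear fit) reports `p = NA` and
  is excluded from significance rather than being called infinitely
  significant.
* **Intensity round trip.** `generateIntensities()` defaults to a total of
  $2^{20}-100$ so that $\beta\,(T+100)$ is an exact binary scaling and
  `computeBeta()` recovers the input bit for bit.
* **Rank tests.** `stats::wilcox.test` conventions: exact p-values for
  small tie-free samples, normal approximation with continuity correction
  otherwise; mid-ranks for ties.
* **Determinism.** One run seed governs simulation, fold assignment and
  every stage, with per-stage seeds derived deterministically; k-fold
  assignment is tied to sorted sample IDs and leave-one-dataset-out fold
  seeds to dataset labels, so predictions are invariant to sample and
  dataset ordering. Pipeline TSVs are written with fixed formatting and a
  rerun of the same configuration reproduces them byte for byte.

# Surrogate components

Two preprocessing steps published as externally defined procedures are
implemented as deliberately simple, fully testable surrogates and labelled
as such in their documentation:

* **Sex estimation** scores each sample by the fraction of X-chromosome
  betas in (0.2, 0.8) and splits the scores by 1-D 2-means (females high,
  by X inactivation). On simulated cohorts with realistic noise it recovers
  over 99% of labels.
* **Density QC** replaces a manual inspection of per-sample beta densities
  with a deterministic mid-beta mass score (fraction of autosomal betas in
  [0.25, 0.75]; bimodal methylomes score low) and a configurable threshold,
  so exclusions are reproducible and logged.
* **Fixed-reference quantile normalization** rank-maps each sample onto
  stored per-design-type reference quantiles (pooled empirical quantiles of
  a reference cohort, serialized with the run). It preserves within-sample
  ranks, is idempotent on a sample already matching the reference, and
  removes distribution-level batch shifts; it does not attempt the cited
  between-design calibration of dasen-style methods, and per-CpG batch
  offsets that cancel within a sample's distribution are intentionally out
  of its reach (they are handled by the batch covariate in the EWAS).

# Problem sizes used by the test and acceptance runs

Slope-recovery scenarios use 400 paired samples with a 201-CpG shared panel
at noise sd 0.005; calibration checks use 20 replicates of 2000 null CpGs by
200 samples; the full-preset verdict check runs the complete
EWAS-partition-rates pipeline on 20 seeded replicates of the default
~9.8k-CpG, 404-subject cohort. These sizes were chosen as the smallest at
which the quantities being checked are stable to well within their test
tolerances.

# Known limitations

* The EWAS models age linearly on untransformed years; nonlinear
  trajectories (common in young cohorts) are out of scope, as are genomic
  inflation correction and surrogate-variable adjustment.
* The slope read-out is quantitative only under the identity transform.
* Cross-tissue verdicts describe rates of methylation change on the chosen
  shared CpGs; the package deliberately reports slopes and tallies, not
  claims that a tissue is "biologically younger".
* Published clock coefficient sets and their bespoke normalizations are not
  reproduced; foreign clocks can be loaded from plain coefficient tables
  with a user-declared transform.
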