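---
title: "Meta-analytic prediction of enteric methane output: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analytic prediction of enteric methane output: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ch4meta)
```

## The problem

Enteric methane (CH4) from cattle is a first-order greenhouse-gas term, but
direct measurement (respiration chambers, SF6 tracer) is expensive and does
not scale. The standard remedy is meta-analytic: collect treatment-mean
records from feeding studies — one row per dietary treatment within a study,
carrying body weight, dry-matter intake (DMI), diet chemistry, energy
intakes, digestibilities and measured CH4 — harmonize their heterogeneous
units and missing fields, regress CH4 energy output (MJ/day) on intake and
diet variables with study-level random effects, and benchmark the resulting
equations (and previously published ones) with a prediction-error
decomposition and concordance statistics. `ch4meta` implements that entire
workflow, plus a calibrated synthetic-database generator so every stage is
testable without access to any proprietary literature database.

## Harmonization calculus

Treatment means are completed through a fixed chain of published identities
and regressions; every filled cell is flagged `derived` (exact arithmetic)
or `imputed` (regression-based), and observed values are never overwritten.

* **GE intake.** When gross-energy intake is unreported it is built from
  diet chemistry: GE (MJ/kg DM) = (23.6 CP + 39.8 EE + 17.3 NFC +
  18.9 NDF)/1000, all in g/kg DM, times DMI.
* **Energy balance.** DEI = GEI − FE and MEI = DEI − CH4 − UE (all MJ/day),
  iterated until no member is derivable; `q = MEI/GEI`. One source formula
  prints the first identity with ME in place of GE on the right-hand side;
  we treat that as typographical (the companion identity is the standard
  balance) and use DEI = GEI − FE. Records whose fully observed identities
  disagree by more than 0.5% (relative) are rejected — published treatment
  means are rounded, so exact equality cannot be demanded.
* **Feeding level.** FL = MEI / ME_m with ME_m = 0.53 (BW/1.08)^0.67 /
  (0.35 q + 0.503). The printed expression is ambiguous in its grouping;
  this is the only parse in which 0.53 acts as a maintenance energy scale
  and FL is dimensionless (FL = 1 at maintenance).
* **Digestibility imputation**, in listed precedence: OM = 40.4 + 0.966 GE;
  GE = 9.6 + 0.84 OM; GE = 16.2 + 0.765 DM (all g/kg), cascaded until
  fixed point.
* **OMDm.** Digestibility falls as intake rises, so observed OM
  digestibility is adjusted to the maintenance feeding level:
  OMDm = OMD + 1.83 (DMI/BW − DMI/BW at maintenance), with the maintenance
  intake ratio 13.8 + 2.195 FL evaluated at FL = 1 (15.995 g/kg).
* **CH4 units.** 0.714 g/L, 39.54 kJ/L, 55.65 kJ/g, 4.184 kJ/kcal, used
  exactly as published. These constants are not mutually consistent
  (0.714 × 55.65 = 39.73 ≠ 39.54), so litre-based values are converted to
  energy through 39.54 kJ/L directly and never chained through grams; each
  from/to pair then round-trips to machine precision. Intensity units
  (g/kg DM, % of GE, ...) use the record's own intake context.

`harmonize()` applies these in a fixed order (closure check, daily-CH4
recovery, GE intake, energy balance, digestibility, FL, OMDm, remaining CH4
units) and is idempotent.

## The synthetic-database generator

No public treatment-level database exists for this analysis, so the
generator is a first-class module, not a test fixture. It emulates:

* **Marginals.** Published per-database summaries give mean, SD, minimum and
  maximum for each variable ([calibration_table()]). Each generator-drawn
  variable uses a truncated normal on [min, max] whose *parent* mean and SD
  are solved (closed-form truncated-normal moments + Nelder–Mead) so that
  the *truncated* distribution has exactly the published mean and SD.
  Naive truncation would not do: truncating N(10.28, 5.86²) to
  [2.29, 26.2] (combined DMI) inflates the mean by ≈ 0.95 kg/day, an error
  ~16 Monte-Carlo SEs at n = 10,000.
* **Composition coherence.** NFC is computed by closure OM − CP − EE − NDF;
  when the closure value leaves the published NFC range the composition
  block (only) is re-drawn, so body weight and intake marginals are
  untouched. ADF is capped at NDF. OM digestibility is drawn negatively
  correlated with NDF (r = −0.5, a structural stand-in for the published
  pairwise correlations), and GE/DM digestibilities derive from it through
  the imputation regressions plus noise, keeping the digestibility set
  internally consistent.
* **The CH4 signal.** CH4 (MJ/day) = true_equation(record) + study
  intercept + study slope × DMI + residual, floored at 0.1 MJ/day. The
  default true equation per database is the corresponding DMI-only
  developed linear equation — DMI is the best single predictor in this
  literature. All other CH4 units derive from the MJ/day value through the
  conversion calculus; energy fields (GEI from chemistry, DEI from GE
  digestibility, an ME:DE ratio of 0.729 ± 0.05 calibrated to the published
  energy means, UE back-derived) satisfy the balance identities exactly.
* **Noise defaults** (not published anywhere; chosen once): study intercept
  SD 1.0 MJ/day, study slope SD 0.1 (MJ/day)/(kg/day), residual SD equal to
  the reported RMSE of the database's DMI-only equation (beef 2.13, dairy
  2.73, combined 3.04 MJ/day). For the combined database these reproduce
  the published overall CH4 SD (≈ 7.0 MJ/day) almost exactly. The residual
  SD of a treatment mean scales as sqrt(10/n_animals) — means over more
  animals are less noisy, the same precision structure the animal-count
  regression weights assume. Animal counts are uniform on 4–16 and
  treatments-per-study uniform on 3–6; neither distribution is published,
  and both are documented placeholders.
* **Determinism.** A single integer seed fully determines the output.

What the generator does *not* emulate: between-study heterogeneity in diet
design (marginals are common across studies except through the shared
random effects), the full correlation matrix of diet chemistry (only the
structurally induced correlations above), and any breed/geography
structure. Tests passing on synthetic data therefore certify the
*machinery* — estimator calibration, identities, rankings — not the
field-level accuracy of any equation.

## Model development

* **Outlier screen.** Cook's distance from the weighted fixed-effects
  regression; the screen *reports* records with D > 4/n (an explicit,
  testable replacement for visual inspection of the D distribution; the
  cutoff is configurable).
* **Mixed linear model.** REML fit of
  Y_ij = B0 + B1 X_ij (+ B2 X_ij²) + s_i + b_i X_ij + e_ij, with study
  random intercept s_i and slope b_i, weighted by animal count (weights are
  normalized to mean one, so estimates are scale-invariant and the residual
  SD reads on the observation scale). The unstructured intercept–slope
  covariance is fitted first; when it fails to converge or the covariance
  is non-significant (LRT, α = 0.10) the variance-components structure is
  used; a degenerate random structure falls back to weighted OLS.
* **R² convention.** The squared correlation between the observed response
  and the *fixed-effects* predictions. Published tables never define their
  R²; any comparison across conventions (e.g. conditional R²) is unsafe.
* **Backward elimination.** Candidate sets with any VIF ≥ 10 are rejected
  before fitting (VIF from explicit auxiliary regressions; exact
  collinearity reports Inf). Terms with fixed-effect p > 0.10 are removed
  worst-first, one per refit; the primary predictor may only leave if its
  random slope is also non-significant. The trace of every fit and decision
  is returned and is deterministic given the data. Note a structural
  consequence: with k truly inactive candidates, all-noise variables
  survive with probability ≈ α each, so "true model selected" succeeds with
  probability ≈ (1−α)^k ≈ 0.81 for k = 2 at α = 0.10 — a property of the
  removal rule itself, not of the implementation.
* **Nonlinear models.** Monomolecular a − (a+b)e^(−cx) (the Mitscherlich is
  its b = 0 special case), Gompertz
  b·exp[(1 − e^(−cx)) ln((a+2b)/b)] − 2b (value −b at x = 0, asymptote a),
  exponential b·e^(cx) and power b·x^c, fitted with study-level random
  parameters richest-first (all parameters diagonal-random, then random b,
  then fixed-effects nonlinear least squares), starting values from a
  deterministic log-spaced grid over data-driven bounds. Published
  exponential rows print a negative b, which would force negative methane;
  |b| is used, the anomaly is flagged per equation, and a `literal_sign`
  switch restores the printed sign for audit. The model with minimal BIC is
  selected, ties broken toward fewer parameters.

## Evaluation

All second moments are population (divide-by-n) SDs, so the decomposition
identity is exact rather than approximate:

* MSPE = Σ(O_i − P_i)²/n; RMSPE% = 100·√MSPE / mean(O).
* ECT = (P̄ − Ō)² (mean bias), ER = (S_p − r·S_o)² (slope bias),
  ED = (1 − r²)·S_o² (random error); ECT + ER + ED = MSPE identically.
* CCC = r · Cb with Cb = 2/(v + 1/v + μ²), v = S_o/S_p and
  μ = (Ō − P̄)/√(S_o·S_p). The sign convention makes μ negative exactly
  when the model overpredicts. v and μ follow Lin's standard definitions
  (the source names them without formulas). The direct form
  2·r·S_o·S_p/(S_o² + S_p² + (Ō − P̄)²) is algebraically identical and is
  used as an independent cross-check in the tests.
* Per-equation record dropping: an equation is evaluated on exactly the
  records that carry all its required predictors (no evaluation-time
  imputation), with `n_used` reported.
* The correlation screen reports Pearson r, its two-sided p and R² = r²;
  published screen tables carry an R² column that is not r² and whose
  derivation is unknown — it is not imitated.

## Numerical and degenerate-input choices

* Energy-identity tolerance 0.5% relative; composition closure tolerance
  20 g/kg — both sized to the rounding of published treatment means.
* Constant predictions: the decomposition folds everything except the mean
  bias into ED (r is undefined at S_p = 0); CCC is reported NA.
* Zero-variance series, length mismatches and nonpositive observed means
  raise errors rather than returning NaN.
* Truncated-normal sampling is inverse-CDF (exact, vectorized,
  reproducible); moment matching minimizes standardized squared error and
  returns its residual, so unreachable (mean, SD, range) triplets degrade
  gracefully to the best family member.

## Problem sizes used by the packaged checks

The packaged test-suite and acceptance script use: 10,000 records
(2,000 studies × 5) for calibration checks; 34 studies × 3–6 treatments
(≈ 150 records, the scale of the motivating literature database) for
parameter-recovery replicates (50 seeds) and elimination runs (20 seeds);
1,000 random vectors for the identity properties. These sizes were chosen
so Monte-Carlo error is small relative to each tolerance.

## Known limitations

* The generator's correlation structure is partial (see above); equations
  using predictors other than DMI are evaluated on synthetic data whose
  joint distribution is simpler than real diets.
* Mixed-model p-values use Satterthwaite approximations (fixed effects) and
  boundary-naive LRTs (random components, conservative); alternative
  df corrections would shift borderline eliminations.
* The registry stores published coefficients verbatim, including internal
  inconsistencies of their sources (e.g. running-text R² values that
  disagree with the tabulated ones); it does not attempt reconciliation.
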