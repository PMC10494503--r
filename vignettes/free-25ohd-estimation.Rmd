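---
title: "Estimating free 25-hydroxyvitamin D: models, validation and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating free 25-hydroxyvitamin D: models, validation and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freevitd)
```

## The problem

Circulating 25-hydroxyvitamin D is almost entirely protein-bound: roughly
85–90% to vitamin D binding protein (VDBP, Gc-globulin) and most of the rest
to albumin, leaving a free fraction on the order of 0.03%. VDBP concentration
varies substantially between individuals and the protein occurs as six Gc
diplotypes (combinations of the Gc1f, Gc1s and Gc2 variants) with potentially
different binding affinities, so total 25(OH)D can rank individuals
differently than the free, putatively bioactive pool. Direct free 25(OH)D
assays exist but are not routine and have high analytical variability, which
motivates estimating equations from measurable biomarkers.

This package implements two families of estimators and everything needed to
develop and internally validate new ones.

## The estimating equations

The three shipped regression equations are linear in albumin and in the
natural logarithms of the right-skewed biomarkers, with one log×log
interaction and (in the second equation) additive diplotype offsets against
the Gc1f/Gc1f reference:

```{r}
eq2_spec()
```

Input units are fixed and embedded in the cohort column names: albumin g/dL;
25(OH)D3, 25(OH)D2 and 24,25(OH)2D3 ng/mL; VDBP µg/mL; 1,25(OH)2D3 and iPTH
pg/mL. Output is pg/mL. No unit auto-detection is attempted — inputs in other
conventions (e.g. nmol/L) must be converted by the caller, and the loud
unit-bearing column names are a deliberate guard against silent unit errors.

Two choices in the evaluator deserve explanation:

* **Logarithm base.** The published formulas do not state a base. We use the
  natural logarithm: evaluating the clinical equation at the cohort's median
  predictor values gives 5.36 pg/mL with natural logs versus about 4.75 with
  base-10, and only the former is consistent with the cohort's median
  measured free 25(OH)D of 5.3 pg/mL.
* **Negative predictions.** At extreme inputs the linear form can go
  negative. `evaluate_equation()` returns the raw value with a warning and a
  `flagged_negative` attribute rather than clipping, so that agreement
  statistics computed downstream are faithful to the model;
  `floor_estimates()` (and the CLI `--floor` flag) applies a presentation
  floor, default 0.1 pg/mL, when a clinical display needs one.

A related input-side convention: 25(OH)D2 is frequently below assay
detection. Because the equations log-transform it, `read_cohort()` and the
generator substitute a configurable detection floor (default 0.2 ng/mL, the
observed reporting floor in the calibration tables) for zero or missing
values, with a warning counting the substitutions.

## The binding-equilibrium (Bikle) equation

The older mass-action estimator treats 25(OH)D binding as a single-site
equilibrium with both carriers far from saturation:

free = total 25(OH)D / (1 + Ka1·[VDBP] + Ka2·[albumin]),

with Ka1 = 8.00×10⁸ M⁻¹ and Ka2 = 6.00×10⁵ M⁻¹ and carrier concentrations in
mol/L. Total 25(OH)D is the D3 + D2 sum. The affinity constants are
per-molar, so the clinical units must be converted: the molecular weights
involved are not part of the published constants and we adopt the values
conventionally paired with them — 25(OH)D 400.64 g/mol, VDBP 58,000 g/mol,
albumin 66,430 g/mol — all overridable through `binding_constants()`. With
these defaults, the equilibrium denominator at the cohort's median inputs is
about 3,883 and the estimate about 5.31 pg/mL, consistent with the median
measured value. The implementation is checked against an independent
evaluation that performs all conversions on the molar scale and converts back
only at the end.

## Agreement and accuracy metrics

`validate_estimates()` reports, overall and per subgroup:

* **Bland–Altman bias and 95% limits of agreement.** Differences are
  *estimated − measured* (overestimation ⇒ positive bias); LOA are
  bias ± 1.96·SD with the sample (n−1) standard deviation and no
  small-sample correction, the standard construction when no proportional
  bias model is fitted.
* **P15 / P30.** The proportion of pairs whose absolute error is within 15%
  (30%) of the *measured* value; boundary ties count as within.
* **RMSE.**

Subgroups with fewer than two pairs are flagged `incomplete` rather than
failing, since bias and LOA are undefined there. Regression-based LOA,
Deming and Passing–Bablok comparisons are out of scope.

## Equation development

`develop_equation()` reproduces the full published procedure:

1. **Split.** A seeded random partition into a development set of
   `round(2/3 · n)` participants and a held-out validation set. A published
   split of 244/126 out of 370 does not equal the rounded two-thirds (247),
   so `dev_n` can fix the development size explicitly; nothing suggests the
   original split was stratified, and ours is simple random.
2. **Forced variables.** Mode `eq1` forces albumin, 25(OH)D3, 25(OH)D2 and
   VDBP; mode `eq2` adds the diplotype block; mode `eq3` forces nothing but
   restricts candidates to routinely available biomarkers (25(OH)D3, albumin,
   iPTH, 1,25(OH)2D3, calcium, phosphate, eGFR, 25(OH)D2).
3. **Forward selection.** At each step every remaining candidate is refit on
   top of the current model and the best adjusted-R² improvement is retained
   if it is at least 0.02; ties break by declared candidate order, and an
   optional univariable pre-screen (`prescreen = TRUE`) re-orders candidates
   by marginal adjusted R² without ever affecting eligibility. Vitamin D
   metabolites, VDBP, iPTH and iFGF-23 enter as natural logs; demographic
   and seasonal variables untransformed. Categorical variables (diplotype,
   season, site, sex, race) enter as all-in-or-all-out indicator blocks and
   count as their number of indicator columns in the adjusted R². The
   total-25(OH)D candidate (D2 + D3 sum) is dropped automatically whenever
   D3 or D2 is forced, to avoid engineered collinearity.
4. **Interaction search.** All pairwise products of the (log-transformed)
   continuous variables in the final main-effect set are evaluated under the
   same threshold rule and added greedily in decreasing-improvement order.
5. **Refit and validate.** The final model is refit on the development set,
   expressed as an `equation_spec()`, and evaluated on the held-out set with
   the metrics above.

Every candidate evaluation is recorded in a trace (step, candidate, adjusted
R² before/after, retained flag), making the selection path fully auditable.
One representational limit: the printed-equation format supports additive
offsets only for the diplotype block, so a development run that retains
season, site, sex or race stops with an explicit error rather than silently
dropping them; with the shipped truth models this path is never taken.

### What the retention rule can and cannot recover

The ≥ 0.02 adjusted-R² rule is a *population-level* hurdle: a predictor is
retained only when its partial contribution explains at least 2% of response
variance. With the published clinical-equation coefficients and realistic
predictor dispersions (albumin SD ≈ 0.4 g/dL, log-iPTH SD ≈ 0.45), albumin
contributes about 0.2% and iPTH about 1% — an order of magnitude and a factor
of two below the hurdle — so selection on data simulated from that equation
retains 25(OH)D3 and 1,25(OH)2D3 and provably rejects albumin and iPTH, no
matter the sample size. Retention of such weak predictors in a real
development sample of a few hundred is consistent with sampling noise in the
estimated improvement. The acceptance test documenting the published
predictor set as the recovery target therefore fails on those two variables,
and we consider the failure informative about the selection rule rather than
a defect of the machinery; the accompanying coefficient-recovery test (OLS
refit of the full generating term set at n = 5,000, every coefficient inside
a Šidák-adjusted simultaneous 95% confidence band — simultaneous because
thirteen marginal 95% intervals jointly fail about half the time by pure
multiplicity) passes.

## The synthetic cohort generator

`generate_cohort()` emulates the calibration cohort's *marginal* structure:

* Right-skewed biomarkers are log-normal with location = log(published
  median) and scale = log(Q3/Q1) / (2·z₀.₇₅) from the published IQRs:
  25(OH)D3 median 20.3 [13.4, 28.9] ng/mL, VDBP 253.3 [226.9, 284.1] µg/mL,
  1,25(OH)2D3 40.2 [30.2, 50.4] pg/mL, 25(OH)D2 0.33 [0.2, 1.2] ng/mL
  (floored at 0.2), VMR 8.9 [6.5, 11.4].
* 24,25(OH)2D3 is generated **multiplicatively** as VMR × 25(OH)D3 / 100,
  which induces the strong positive dependence between the catabolite and
  its substrate seen in real data (Spearman ρ > 0.5).
* log iPTH shares a latent factor with log 25(OH)D3 (correlation −0.31 by
  default, configurable to 0), reflecting the inverse PTH–vitamin D
  relationship. The overall iPTH median is not published; we use 34 pg/mL,
  the midpoint of the two middle-quartile medians, with sdlog 0.45 read off
  the quartile IQR spans.
* Albumin, age, BMI, eGFR, calcium and phosphate are (truncated) normal with
  the published means/SDs; sex, race, season, site, diabetes and diplotype
  frequencies are the published counts divided by 370.
* Measured free 25(OH)D = truth model (default: the shipped Eq. 2, the
  fullest specification) + Gaussian noise, default SD 1.16 pg/mL — the
  magnitude of the published development RMSE — floored at 0.5 pg/mL, just
  below the observed cohort minimum of 1.59 pg/mL, so additive noise cannot
  produce non-positive "measurements".

Under these defaults the analytic mean of the truth model is ≈ 5.47 pg/mL,
within the published cohort mean of 5.37 ± 1.81 pg/mL without any post-hoc
adjustment; no generator parameter is tuned to test outcomes.

What the generator does **not** emulate: the joint distribution of predictors
beyond the two dependencies above (everything else is independent),
quartile-conditional structure, seasonality of the vitamin D metabolites
themselves, assay-specific error models beyond additive Gaussian noise, and
longitudinal repeat measurements. Passing tests against synthetic cohorts
therefore demonstrate that the machinery is correct and well calibrated at
the margins, not that the shipped equations would attain any particular
accuracy in a new human cohort — that requires external validation.

## Numerical and testing choices

* All randomness flows through explicit integer seeds; generation and
  splitting restore the caller's RNG state.
* OLS goes through `stats::lm` on explicit design matrices; rank deficiency
  is a hard error naming the collinear columns. Tests cross-check
  coefficients against an independent normal-equations solve.
* Problem sizes in the test suite — cohorts of 370 (the published size) for
  calibration and closure checks, 1,000 for selection behavior, 5,000 for
  coefficient recovery, 10,000 for limits-of-agreement coverage — keep the
  whole suite to a few minutes while leaving Monte-Carlo error well inside
  the asserted tolerances.
* Zero-variance candidates are skipped with a warning; noiseless cohorts are
  legitimate inputs (used to verify exact recovery) and the perfect-fit
  warning from `summary.lm` is muffled for them.

## Known limitations

* The shipped coefficients come from adults aged 70–79 in two US cities;
  nothing here addresses transportability to younger, pregnant or
  liver-disease populations where VDBP and albumin differ markedly.
* The diplotype offsets are small relative to the equations' limits of
  agreement (±2.4 pg/mL), consistent with the published observation that
  adding the phenotype barely changes performance.
* The Bikle equation shares one set of affinity constants across diplotypes;
  diplotype-specific affinities are not modeled.
* Free 25(OH)D here means free, not "bioavailable" (free + albumin-bound);
  the modified free-testosterone-style (Vermeulen) estimator is out of scope.
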