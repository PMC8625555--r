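---
title: "Estimating the glycemic load of mixed meals from postprandial glucose curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the glycemic load of mixed meals from postprandial glucose curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glload)
library(dplyr)
```

## The problem

The glycemic index (GI) of a food is the incremental glucose response it
provokes relative to a carbohydrate-matched sugar reference, and the
glycemic load (GL) scales that index by the serving's available
carbohydrate. Both are routinely tabulated for single foods, but most
eating — especially of commercial ready-to-eat (RTE) meals — mixes
carbohydrate with fat, protein and fiber, all of which blunt the glucose
response. `glload` implements an analysis pipeline for exactly this
setting: it derives iAUC, GI and GL from measured fingertip-glucose
trajectories in a crossover feeding study, cleans the records, fits a
repeated-measures model of iAUC on nutrient composition, links iAUC to GL
with a second regression, and composes the two fits into a single formula
that estimates a mixed meal's GL from nothing but its nutrition label.

## Incremental area under the curve

Glucose is sampled at 0, 15, 30, 45, 60, 90 and 120 min after the first
bite; the reading at 0 min is the fasting baseline. `incremental_auc()`
integrates the piecewise-linear interpolant of the trajectory, counting
only area **above** baseline (the incremental, cut-off method standard in
GI determination): segments below baseline contribute nothing, and a
segment crossing the baseline contributes only its triangular part above
it. The integral is computed exactly, interval by interval, not on a
refined grid; tests verify it against fine-grid (0.001 min) numerical
integration to a relative error below $10^{-6}$.

Two conventions are fixed deliberately:

* the baseline is the single reading at $t = 0$ (the protocol records one
  fasting value; no averaging);
* integration stops at the last grid point, 120 min; no extrapolation.

## GI, GL and the reference

Each participant drinks the sugar solution twice at every carbohydrate
tier (25, 50, 75 g). GI is computed **within participant**:

$$\mathrm{GI} = 100 \times
  \frac{\mathrm{iAUC}_{\text{meal}}}{\overline{\mathrm{iAUC}}_{\text{sugar, same tier, same participant}}},$$

never as a ratio of meal-level means — this is why a table of meal-mean
iAUCs cannot exactly reproduce tabulated mean GIs. GL uses available
(net) carbohydrate, total carbohydrate minus dietary fiber:

$$\mathrm{GL} = \mathrm{GI} \times \frac{\text{carb} - \text{fiber}}{100}.$$

Reported integer GI/GL values round half away from zero
(`round_half_away()`), matching how the study table was typeset. The
packaged table ships verbatim in `rte_meals()`; `gl_consistency()` checks
each printed GL against GI × available carbohydrate / 100 and flags rows
differing by more than 0.5 — differences arise legitimately because the
upstream analysis averaged unrounded per-participant GLs.

## Cleaning rules

`apply_exclusions()` drops, in this order of precedence, records with

1. fiber > 13 g **and** iAUC > 4000 mg·min/dL (a conjunction: a high
   response despite high fiber),
2. GI < 10,
3. GI > 100.

All inequalities are strict, so GI exactly 10 or 100 is retained, and a
record failing several rules is counted under the first. Filtering is at
the record (participant × meal) level, since GI is a per-participant
quantity; the report object makes the audit trail explicit.

## The two-stage model and its working scale

Stage one fits a repeated-measures linear mixed model of iAUC on
available carbohydrate, fat, protein² and fiber², with a random intercept
per participant (REML via `lmerTest::lmer()`; protein and fiber enter
squared only, with no linear terms and no model selection). Stage two
regresses GL on iAUC by ordinary least squares (`fit_gl_bridge()`),
record-level by default with a meal-level option. Composing the two
(`compose_gl_formula()`) yields the label formula

$$\mathrm{GL} = \alpha + \beta\,(b_0 + b_1\,\text{availCarb} +
   b_2\,\text{fat} + b_3\,\text{protein}^2 + b_4\,\text{fiber}^2).$$

**Working scale.** The published coefficient sets — iAUC intercept 37.05
with +0.35 per gram of carbohydrate, and a bridge GL = −22.07 + 1.12 ×
iAUC — only cohere dimensionally if iAUC enters the models in units of
100 mg·min/dL (a raw iAUC of ~4200 mg·min/dL maps to GL ≈ 25 on that
scale, a sensible value; on the raw scale it would map to GL ≈ 4700).
`glload` therefore stores raw mg·min/dL everywhere and fits on the /100
scale (`iauc_scale = 100`). With that convention the package reproduces
every published coefficient from synthetic data generated under them.

**Inference.** Fixed effects are reported with Wald *t* statistics using
Satterthwaite degrees of freedom. In this grouped crossover design each
participant eats only their group's eight meals, so part of the
carbohydrate contrast is between-participant; normal-quantile intervals
are then anti-conservative (simulation under the generating model put
their coverage near 89%), while Satterthwaite *t* intervals restore
near-nominal coverage. Degenerate inputs fall back to OLS with a warning:
a single participant, an exactly linear (noiseless) response, or a fitted
participant variance collapsing to zero.

**Composition precision.** Composition is exact:
$\alpha + \beta b_0$, $\beta b_i$. Composing the *rounded* published
stage estimates gives intercept 19.426 and fat coefficient −0.2016,
whereas the published composed formula prints 19.27 and −0.21 — the
upstream composition evidently used unrounded estimates, which are not
recoverable from the printed two-decimal values. `glload` composes at
full precision, serialises formulas to JSON at full double precision, and
treats rounding purely as display. The frozen published formula is
available as `published_gl_formula()` (version tag `published-2021`).

`validate_predictions()` closes the loop: an OLS of measured mean GL on
predicted GL across meals, with slope, intercept, R² and an `autoplot()`
method. Predictions for labels whose available carbohydrate falls outside
20–103 g (the span of the packaged meal table) carry an extrapolation
warning, as do negative predictions.

## What the synthetic generator emulates

No individual-level data are deposited for this design, so
`simulate_study()` regenerates the study skeleton with known truth:

* 34 participants in 4 groups (9/9/8/8), each consuming their group's 8
  meals of the packaged 32-meal table; every meal is eaten by at least 8
  participants;
* 6 sugar references per participant (2 repeats × 3 tiers);
* fasting baseline per participant ~ Normal(92.5, 5.4²) mg/dL, the
  cohort's fasting glucose distribution;
* meal-test iAUC target = 100 × (published linear predictor) +
  participant intercept + test noise, truncated at zero (truncation is
  reported and is essentially absent at the defaults);
* each curve is a single-peak excursion
  $\Delta g(t) = A\,(t/t_p)\,e^{1 - t/t_p}$ with $t_p = 30$ min, the
  amplitude solved so the trapezoidal iAUC of the 7-point curve equals
  its target exactly. The shape never dips below baseline, rises and
  declines like observed group-mean curves, and makes iAUC exactly
  controllable — which is what parameter-recovery testing needs.

Calibration defaults the underlying study does not pin down, chosen once
and not tuned:

* participant intercept SD 400 and residual SD 500 mg·min/dL — the study
  reports only meal-level SDs, so these are free defaults of plausible
  magnitude relative to meal iAUC means of ~4000–6000 mg·min/dL;
* reference-tier mean iAUCs 6600/7600/9000 mg·min/dL for 25/50/75 g.
  These are set so that the simulated GI distribution centres near 65,
  mid-range of the printed study GIs. They are deliberately *larger*
  than the printed sugar-reference iAUCs (≈2750–6000): the published
  generating equation predicts meal iAUCs above those reference levels,
  and references in that printed range would push nearly all simulated
  GIs past 100, where the GI ≤ 100 cleaning rule would empty the dataset.
  The mismatch is a documented property of the published equation, not of
  the simulator;
* reference variability: participant-level CV 10% shared by a
  participant's duplicates, plus a 5% repeat-level CV so duplicate
  averaging is exercised.

What the generator does **not** emulate: within-day baseline drift,
meal-by-participant interaction, curve-shape diversity (double peaks,
below-baseline rebounds), sex or menstrual-cycle effects, or day-to-day
reference drift. Passing recovery tests therefore demonstrate that the
estimators are correct under the stated model, not that the model
captures every feature of real glycemic data.

## Numerical and design choices

* Determinism: `simulate_study()` seeds R's RNG from `config$seed`; the
  same configuration regenerates byte-identical CSV output.
* The excursion amplitude is linear in the target, so the solve is exact
  (no iteration); a zero target gives a flat curve at baseline, which is
  valid and yields iAUC 0.
* Boiled-rice reference curves, where present in input files, pass
  through I/O untouched; the GI denominator is always the sugar solution.
* Missing sugars values parse as `NA` and never enter any computation
  (the formula has no sugars term).
* Tier matching uses the explicit `tier_g` column, never nearest-dose
  inference.
* The bridge is record-level by default (preserving sample size);
  `level = "meal"` averages per meal first, for sensitivity analysis.

Test problem sizes: the oracle-equivalence property uses 1000 random
curves against a 0.001-min numerical grid; parameter recovery uses 20
replicate studies at the full design size (272 meal tests each), which
keeps the whole suite comfortably within a few minutes on one core.

## Limitations

The published two-stage fit pooled this study with an earlier one whose
records are unavailable; consequently the *numerical* agreement
demonstrated here is between the package and synthetic data generated
under the published coefficients, not a re-derivation of those
coefficients from raw human data. The measured-versus-predicted
calibration of the original report (slope 1.7, R² 0.73) likewise depends
on the unavailable pooled records; the package reports its own validation
regression on whatever data it is given and deliberately does not
recalibrate predictions.
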