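---
title: "Scoring and evaluating ILD-GAP and ILD-GAPM: models, simulation and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and evaluating ILD-GAP and ILD-GAPM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ildgapm)
```

## The scoring models

The ILD-GAP index summarises the prognosis of a patient with fibrosing
interstitial lung disease (ILD) from four bedside quantities: **G**ender,
**A**ge, and two **P**hysiology measurements, the percent-predicted forced
vital capacity (%FVC) and the percent-predicted carbon-monoxide diffusing
capacity (%DLco). Points accumulate as follows: male sex 1; age in
(60, 65] years 1, above 65 years 2; %FVC in [50, 75] 1, below 50 2;
%DLco in (35, 55] 1, at or below 35 2, and 3 when the DLco manoeuvre
cannot be performed at all. Patients whose subtype is CVD-IP, iNSIP or
chronic hypersensitivity pneumonitis receive a −2 adjustment relative to
IPF and unclassifiable ILD, so the total spans −2 to 8.

ILD-GAPM adds a single haematology point: 1 when the blood monocyte ratio
(monocytes as a percentage of leukocytes) exceeds 8.5%, extending the
range to 9. The 8.5% cut is a **fixed model constant** — the median of the
model's development cohort — and is deliberately not recomputed per
cohort; `score_cohort(..., monocyte_cut = "median")` exists for
sensitivity analyses only. Totals map to stages by I ≤ 1 < II ≤ 3 <
III ≤ 5 < IV, identically for both models.

Two numerical conventions matter for real-valued covariates:

* **Bin edges.** The printed tables use integer-looking bins
  ("61–65", "36–55"). We partition the real line so every value maps to
  exactly one bin and integer inputs reproduce the printed table: age
  ≤ 60 / (60, 65] / > 65, %FVC > 75 / [50, 75] / < 50, %DLco
  > 55 / (35, 55] / ≤ 35. In particular a DLco of 35.5 falls in the
  1-point bin: the table's "≤ 35" anchors the 2-point bin, and a closed
  [36, 55] would leave (35, 36) unmapped.
* **Missing vs unmeasurable DLco.** The 3-point bin encodes the clinical
  inability to perform the manoeuvre, not missing data. A blank
  `dlco_pct_pred` is therefore a schema error unless the row carries the
  explicit `dlco_unmeasurable = 1` flag.

HRCT involvement is summarised by the six-zone semiquantitative scheme:
each of six lung zones (upper/middle/lower, both lungs) receives an
extent grade 0–4 per abnormality (ground-glass opacity and honeycombing
separately) and the global score is their sum (0–24). Published versions
of the scheme differ in the percent-extent bin edges and this package
does not adjudicate them: `grade_from_extent()` defaults to extent
quartiles (0, (0,25], (25,50], (50,75], (75,100]) and exposes the
thresholds. Grading from images is out of scope; grades are consumed as
integers.

## The synthetic cohort

No patient-level data accompany the model, so the package ships a
generator whose defaults emulate the development cohort's structure: 179
patients; subtype mix 56:112:6:5 for IPF : CVD-IP/iNSIP : CHP : UC-ILD
(the lumped class is split evenly between CVD-IP and iNSIP — both take
the same −2 adjustment, so scoring is unaffected); subtype-specific male
fractions (0.88, 0.57, 0.67, 1.00); age 73 ± 9 y; %FVC 94.2 ± 18.8;
%DLco 92.9 ± 30.5; monocyte ratio 8.6 ± 2.8%. Continuous covariates are
truncated normals (age ≥ 18, positive physiology and monocyte values)
drawn by resampling rather than clipping, which keeps the densities
smooth at the bound. The absolute monocyte count is derived as
ratio × a simulated leukocyte count (≈ 6,700/µL), reproducing the
reported ≈ 574/µL mean; the comorbidity index is Poisson(2) and the HRCT
global scores are negative-binomial with subtype-dependent honeycomb
means — all three are artifact choices where no distributional
information exists, and none of them feeds the event model.

Event times follow a proportional-hazards law with hazard
$h(t) = h_0\, s\, t^{s-1} \exp(\beta\,\mathrm{score} + \epsilon)$, where
the score is the subject's integer ILD-GAPM total (option
`truth_score = "ild_gap"` drops the monocyte point from the truth, making
it pure noise), $\beta$ defaults to $\log 1.35$ per point, the Weibull
shape $s$ defaults to 1 (exponential — the closed forms below are exact
there, and nothing in the emulated study constrains the hazard shape),
and $\epsilon$ is optional normal frailty noise for robustness
experiments. Follow-up is administratively censored at 1,095 days with
additional exponential dropout.

Two calibrations tie the generator to its target conditions:

* **Dropout rate.** With total exit rate $\rho$ (dropout + marginal
  events) the mean follow-up truncated at horizon $a$ is
  $(1 - e^{-\rho a})/\rho$; solving this for the 679-day target and
  subtracting the marginal event rate implied by the 12% event fraction
  gives the dropout rate in closed form. Ignoring the event competition —
  the naive calibration — would depress the realised mean follow-up by
  roughly 9%.
* **Baseline hazard.** `calibrate_baseline_hazard()` draws one large
  Monte-Carlo sample of covariates, unit-exponential event variates and
  dropout times under a fixed internal seed; the observed event fraction
  is then a deterministic monotone step function of $h_0$ and is solved
  by bisection on the log scale. The shipped default
  ($h_0 = 9.093 \times 10^{-5}$/day) is the output of this calibration at
  the 0.12 target, and the test suite re-checks the realised 3-year event
  fraction at n = 50,000 against 12% ± 0.5 points.

One global seed spawns three sub-seeds (covariates, event times,
censoring), so each sub-stream is independently reproducible and the
whole cohort is byte-identical under a fixed seed.

What the generator does **not** emulate: correlations between covariates
(e.g. the real cohort's lower %DLco among IPF patients), time-varying
monocyte counts, competing non-ILD deaths, and informative censoring.
Passing tests therefore demonstrate that the estimators and the pipeline
behave correctly under a faithful proportional-hazards null/alternative —
not that the published cohort-specific estimates are recoverable, which
without the patient data they are not. The default conditions give
moderate, clinically realistic discrimination rather than near-perfect
separation, because the discrete score is a coarse summary of the hazard.

## The evaluation stack

All estimators are implemented from first principles (the `survival`
package serves only as an independent cross-check in the test suite):

* **Kaplan–Meier** product-limit curves; tied events decrement
  simultaneously and subjects censored at an event time remain in that
  risk set.
* **k-group log-rank** with hypergeometric variance; the statistic uses a
  pseudoinverse of the reduced variance matrix so degenerate strata fail
  soft, and single-subject risk sets contribute no variance term.
* **Harrell's C-index**: comparable pairs are those whose shorter
  follow-up ends in an event (plus event/censored pairs tied in time);
  tied scores count 1/2.
* **IPCW time-dependent AUC** (cumulative/dynamic) at a fixed horizon,
  default 1,095 days — "3 years" is interpreted as 3 × 365 days. Cases
  (events at or before the horizon) are weighted by the inverse
  Kaplan–Meier censoring survival just before their event time, controls
  by the inverse censoring survival just before the horizon. Controls
  include subjects censored event-free *exactly at* the horizon, and the
  left limit is used there: under administrative censoring at the horizon
  nobody's follow-up strictly exceeds it, and the right-continuous
  censoring survival would be deflated by the administrative atom itself.
  The cumulative/dynamic IPCW form was chosen because the emulated
  endpoint is itself a fixed-horizon ("3-year event") framing; it is the
  standard estimator for clinical risk scores.
* **Univariate Cox** partial-likelihood fits by Newton–Raphson with
  Efron's tie correction (many ties arise from the discrete score);
  Breslow is available for oracle comparison. The covariate is
  standardised internally for numeric stability and the step is damped at
  5 to avoid overshoot; monotone likelihoods (perfect separation) and
  non-convergence raise errors rather than returning garbage.
  AIC = −2 logPL(β̂) + 2 for the single parameter.
* **Bootstrap CIs**: subjects resampled with replacement, B = 2000 by
  default, normal approximation (estimate ± 1.96 SE). Resamples that lose
  all cases or all controls return `NA` and are dropped from the SE (the
  count is reported); at realistic event fractions this is vanishingly
  rare.

The paired model comparison evaluates ILD-GAP and ILD-GAPM on the
identical subject set with identical bootstrap resample streams (the same
seed starts each model's resampling), so metric differences are not
inflated by resampling noise. The AIC compares Cox fits of the score as a
**continuous covariate** by default. The alternative of entering the
stage as a categorical factor would require a three-coefficient
(multivariable) fit, which the evaluation layer deliberately does not
implement; the provided `aic_mode = "stage"` instead fits the stage as an
ordinal 1–4 covariate, which preserves the single-parameter AIC
comparison while respecting the staging.

The univariate screen fits each predictor (age, sex coded male = 1,
comorbidity index, monocyte ratio, both HRCT scores, the ILD-GAP total,
%FVC, %DLco) separately within IPF and non-IPF strata, reports unadjusted
Wald P values and flags them at 0.05 two-sided — deliberately without
multiple-testing correction, mirroring how such screens are reported.
Strata without events and constant or absent predictor columns are
skipped with warnings, never a crash.

## Problem sizes and reproducibility

Stochastic validation in the test suite uses sizes chosen to make
Monte-Carlo error small relative to the asserted tolerances while keeping
the default run fast: covariate marginals at n = 100,000 (three MC
standard errors), event-fraction calibration at n = 50,000 (±0.5
percentage points), Cox CI coverage of the simulated log hazard ratio
over 100 replicates of n = 2,000 (≥ 90% required), direction-of-effect
comparisons over 60 replicates of n = 600 and 100 replicates at the
development cohort's n = 179. Every stochastic routine takes an explicit
seed and is bit-reproducible; `run_report()` artefacts regenerate
identically from (cohort, plan, seed).

## Known limitations

* Covariates are simulated independently within subtype; real physiology
  and radiology are correlated.
* The competing risk of non-ILD death is folded into censoring, as the
  composite "ILD-related event" endpoint implicitly does.
* The Cox layer is strictly univariate; adjusted hazard ratios are out of
  scope.
* The monocyte cut (8.5%) and the stage cut-offs are fixed constants of
  the implemented models; this package evaluates them but does not
  re-derive them.
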