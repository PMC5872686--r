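---
title: "Lifetime UVR dose, 25OHD deseasonalization and matched case-control models"
author: "helioepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifetime UVR dose, 25OHD deseasonalization and matched case-control models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helioepi)
```

## The scientific problem

Epidemiological studies of multiple sclerosis (MS) and clinically isolated
syndrome (CIS) repeatedly find that people who report more sun exposure have
a lower risk of disease, and that serum 25-hydroxyvitamin D (25OHD) — the
standard circulating marker of vitamin D status — is lower in cases than in
controls, at least in white populations.  Disentangling the two requires a
design in which both exposures are measured on the same subjects and
modelled *simultaneously*: ultraviolet radiation (UVR) drives intradermal
vitamin D synthesis, but it also has immunomodulatory effects that have
nothing to do with vitamin D, and the efficiency of the UVR→25OHD pathway
varies strongly with skin pigmentation.  A matched case-control study across
several race/ethnicity groups is therefore a natural experiment: if vitamin
D is the causal agent, its association with MS should be consistent across
groups; if sun exposure acts through other channels, the UVR association
should persist after accounting for 25OHD.

`helioepi` implements the full analytic chain such a study needs:

1. reconstruction of each subject's **cumulative lifetime ambient UVR dose**
   from residence history, reported leisure-time-outdoors behaviour and a
   monthly latitude-by-month climatology;
2. **deseasonalization** of a single serum 25OHD measurement, so that the
   season of the blood draw does not masquerade as vitamin D status;
3. **mutually adjusted unconditional logistic regression** (both exposures
   in one model) and **matched-set conditional logistic regression**, fitted
   by maximum likelihood with Wald odds-ratio inference;
4. descriptive case-control comparison machinery; and
5. a **synthetic cohort generator** that reproduces the statistical
   structure the analysis assumes, so every stage is testable without
   access to protected individual-level data.

## The dose reconstruction model

For participant $i$ with residence latitude $\ell_i(t)$ and leisure-outdoors
weight $w_i(t) \in [0,1]$, the cumulative dose from age 6 years to the index
date $T_i$ is

$$ D_i \;=\; \sum_{m \,\in\, \text{months}(b_i + 6\,\mathrm{y},\; T_i)}
   A\!\left(\ell_i(m),\, \mathrm{moy}(m)\right) \cdot w_i(m) \cdot f_m , $$

where $A(\ell, k)$ is the ambient erythemal UVR (kJ/m²) of calendar month
$k$ at latitude $\ell$, linearly interpolated between climatology bands, and
$f_m$ is the fraction of month $m$'s days inside the window (1 for interior
months).  Models receive $D_i$ in units of 1000 kJ/m².  The recent-exposure
variables are the same sum restricted to the 12 months before $T_i$, split
into the April–September and October–March months of that window.

Design choices a user should know:

* **Month attribution.** The residence and outdoors interval "in force" for
  a month is the one containing the 15th of that month, with the lookup day
  clamped into the participant's own table coverage.  Because the
  attribution depends only on the calendar month and the participant's
  tables — never on the integration window — dose is *exactly* additive
  over window splits, and scaling all weights by $c$ scales the dose by $c$
  exactly.  Both properties are enforced by tests at 1e-12.
* **Boundary months** are prorated by day count; interior months are never
  sub-divided, because monthly climatology carries no sub-month information.
* **Weighting.** The combination rule between behaviour and ambient dose is
  the simplest faithful one — multiplication — and can be switched off
  (`weighted = FALSE` in `exposure_summary()`) to obtain unweighted ambient
  dose, since published analyses do not always state which variant they
  use.
* **Dates** are calendar dates; ages are exact day counts divided by 365.25.
* The packaged climatology (`default_climatology()`) is **synthetic**: each
  band follows an annual sinusoid peaking in June with mean level and
  amplitude decreasing in latitude, on a realistic ambient erythemal scale
  for the mid-latitude northern hemisphere.  Real satellite grids in the
  same CSV layout drop in via `read_climatology()`.  Season semantics are
  northern-hemisphere (April–September = "summer").

## Deseasonalization of 25OHD

A single 25OHD draw confounds vitamin D status with the season of the
draw.  Two procedures are provided, both operating on the natural-log scale
(log-25OHD is close to normal):

* **Residual method** (`deseasonalize_residual()`): OLS of log-25OHD on a
  season-of-draw indicator (April–September vs October–March) and BMI; the
  adjusted value is the residual plus the grand mean, so downstream odds
  ratios are per log-unit.  BMI is included because adiposity depresses
  circulating 25OHD without (in this design) being a disease risk factor.
  By OLS normal equations the adjusted values are *exactly* orthogonal to
  season and BMI.  The default fitting population is all supplied records
  (the pipeline applies it within race/ethnicity group); pass a subset if a
  controls-only fit is wanted.
* **Control-polynomial method** (`deseasonalize_polynomial()`): a
  polynomial in day-of-year (rescaled to [0,1]) fitted to *controls only*
  within the group; the fitted seasonal deviation (about its control mean)
  is subtracted from every subject, cases included.  Perturbing case values
  therefore never moves the curve.  The default degree is 3: a noiseless
  computation shows the best quadratic leaves 14–27% of an annual cosine's
  fundamental when the seasonal peak is away from mid-year (the
  physiological 25OHD peak is around early August, day-of-year ≈ 0.58),
  while a cubic leaves under 7% across realistic phases.  The validation
  suite requires ≥85% amplitude removal at n = 500 controls.

Threshold coding (`categorize_thresholds()`) follows the clinical
cut-points at 30/50/75 nmol/L applied to the back-transformed adjusted
values; the middle bin is closed on both sides (50.0 and 75.0 both fall in
"50.0–75.0", matching how such bins are printed).  Quintiles
(`quintile_categories()`) are cut at the 20/40/60/80 type-7 percentiles of
the *control* reference distribution, ties assigned to the lower quintile.

## Association models

`fit_logistic()` maximizes the Bernoulli likelihood by iteratively
reweighted least squares with a step-halving safeguard, so the
log-likelihood trace is non-decreasing (exposed as `loglik_trace` and
tested).  Convergence is declared when the largest absolute score component
falls below `tol` (default 1e-8).  Complete or quasi-complete separation
makes the likelihood monotone in some coefficient; the fitter detects the
divergence (|β| > 15 with the score still shrinking) and fails naming the
column, rather than silently reporting a huge finite estimate.  A ridge
fallback (`ridge = λ`) is available for deliberately penalized fits.

`fit_conditional_logistic()` maximizes the matched-set conditional
likelihood
$\prod_s e^{x_{\text{case}}\beta} / \sum_{m \in s} e^{x_m \beta}$
by Newton iteration (log-sum-exp stabilised, step-halved).  Sets whose
members share identical covariate rows carry no information; they are
counted (`n_uninformative`) and excluded, and fitting fails if nothing
informative remains.  On 1:1 pairs with one binary covariate the estimate
equals the discordant-pair ratio exactly; on an intercept + single binary
covariate the unconditional fitter reproduces the 2×2 cross-product ratio
to 1e-10 — both are enforced against independent closed-form oracles.

The study-level wrappers mirror the published modelling choices:

* `mutual_adjustment_analysis()` — one unconditional logistic model per
  group containing cumulative UVR (per 1000 kJ/m²) *and* deseasonalized
  log-25OHD, adjusted for age, sex, smoking, genetic ancestry and
  HLA-DRB1\*15:01 carriage.  Ancestry enters as two of the three fractions
  (African, Amerindian; European dropped) to avoid the sum-to-one
  collinearity.  Facility is a matching key only, never a covariate.
* `threshold_or_analysis()` — conditional logistic over matched sets with
  indicators for the upper 25OHD categories (reference "<50.0"), adjusted
  for age, smoking and BMI.
* `determinants_of_vitd()` — OLS of log-25OHD on recent summer UVR, winter
  UVR, age, sex, BMI and draw season.

Intervals are Wald (z = 1.96); no profile likelihood, and no
multiple-testing correction is applied anywhere — both choices mirror
conventional reporting in this literature.  ORs are accompanied by the
scale note they are valid on (per 1000 kJ/m², per log-unit, or vs a
reference category).

## What the synthetic cohort emulates

`sim_config()` + `generate_cohort()` produce a three-group (black /
hispanic / white) 1:1 matched case-control bundle whose defaults *are* the
study conditions the analysis is validated under:

| parameter | default | meaning |
|---|---|---|
| `true_or_uvr` | 0.53 / 0.66 / 0.68 | true OR per 1000 kJ/m² lifetime UVR |
| `true_or_logvd` | 1 / 1 / 0.52 | true OR per log-unit latent 25OHD |
| `uvr_to_vd_efficiency` | 0.0013 / 0.0022 / 0.0025 | log-25OHD per kJ/m² recent UVR |
| `vd_mu` | 4.07 / 4.21 / 4.40 | group log-25OHD intercept (log nmol/L) |
| `vd_sigma` | 0.3 | SD of Gaussian noise on log-25OHD |
| `season_effect` | +0.10 | April–September draw shift on log-25OHD |
| `bmi_effect` | −0.01 | log-25OHD per BMI unit |
| `matching_caliper_years` | 2 | birth-date caliper |
| `pool_factor` | 5 | eligible pool as multiple of cases |
| `n_facilities` | 10 | facility labels (matching key only) |
| `latitude_range` | 32–42° N | residence latitudes, 1–4 intervals |

Group-level covariate distributions (female fraction, age, BMI, smoking,
HLA carrier frequency, ancestry Dirichlet parameters, supplement-use
probabilities by role) default to values matching the published descriptive
table of the design this generator emulates.  Case status is drawn from a
logistic model in lifetime UVR and *latent* log-25OHD (the measured value
minus the draw-season shift), plus nuisance effects of HLA carriage and
smoking.  The linear predictor uses group-centred exposures: with a scalar
intercept and group-specific effect sizes, uncentred exposures would make
the case rate drift across groups through the product of effect and group
mean; centring pins the eligible-pool case fraction at
`plogis(baseline_logit)` (default ≈ 0.30) everywhere while leaving the
slopes — the quantities the validation recovers — untouched.

Controls are matched without replacement on sex, facility and the
birth-date caliper, nearest birth date first, and inherit the case's index
date.  The 5× eligible pool alone would make exhaustion near-certain in
thin sex × facility cells at small cohort sizes (a male case at n = 150 has
roughly two expected eligible controls), whereas the design this emulates
recruited controls per case from a multi-million-member roster.  The
generator therefore recruits an eligible control *on demand* when the pool
has none — a conditional simulation with sex, facility and index date fixed
and birth date uniform inside the caliper, rejected if it comes out a case.
`recruit_on_demand = FALSE` restores the hard failure, which
`match_control()` always raises.

Supplement use is simulated as a post-onset behaviour (more probable in
cases), so the sensitivity analysis
(`sensitivity_exclude_supplement_users()`) has something to exclude;
removal of a case removes its whole matched set.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: reporting and recall error in residence and
outdoors histories; assay measurement error beyond lognormal noise;
non-response and refusal patterns; migration outside the 32–42° band;
southern-hemisphere seasonality; EHR diagnostic misclassification; and any
genetic structure beyond a single HLA carrier flag and smooth ancestry
fractions.  Parameter recovery on this generator demonstrates that the
*estimators* are consistent under the assumed data-generating process, not
that the process is true.

## Numerical choices and degenerate inputs

* Score-based convergence at 1e-8 (50 iterations), quadratic near the
  optimum; validation fits use `tol = 1e-12` when comparing against
  closed forms.
* The conditional likelihood is evaluated with a per-set log-sum-exp shift,
  so large covariate scales cannot overflow.
* Quantile cut-points use type-7 (inclusive linear interpolation);
  duplicated cut-points from heavy ties are collapsed with a warning.
* Cohort CSVs are written with 17 significant digits: the default 15 loses
  the last ulp of a double, which would make a reloaded cohort reproduce
  exposures only approximately.  With lossless writes, deleting
  intermediates and re-running regenerates byte-identical outputs (tested
  via md5).
* Degenerate inputs fail loudly and early: single-season serum tables,
  single-class outcomes, fully concordant matched sets, rank-deficient
  determinant designs (naming the collinear column), residence coverage
  gaps (naming the participant and date), and exhausted matching pools
  (naming the case and the unmet criteria).

## Problem sizes used by the validation suite

The test suite validates parameter recovery on three replicate cohorts of
2000 cases + 2000 controls per group (estimator error taken as the
three-replicate mean, Monte Carlo SE ≈ 0.06 per log-OR) and Wald coverage
on 200 single-group null cohorts of 300 cases each; the exposure engine is
checked against an independently written per-month summation on 50 random
residence/outdoors configurations at relative tolerance 1e-9.  These sizes
were chosen so the whole suite runs in minutes on one core while keeping
Monte Carlo noise well inside the asserted tolerances.

## Known limitations

* The absolute scale of cumulative dose depends on the supplied
  climatology and on how behaviour weights are interpreted; the synthetic
  default targets a realistic *distributional shape* (means ≈ 1.1–1.6 in
  1000 kJ/m² units), not any particular satellite product.
* Conditional fitting requires exactly one case per set; 1:M controls are
  supported, M:N case sets are not.
* Wald intervals can undercover for very sparse categories; the threshold
  analysis drops empty categories rather than penalizing.
* Southern-hemisphere season semantics are not implemented.
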