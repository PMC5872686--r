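# helioepi

Sun exposure, vitamin D and disease risk in matched case-control studies.

`helioepi` is an R package for epidemiological analyses that must weigh two
entangled exposures — ambient ultraviolet radiation (UVR) and serum
25-hydroxyvitamin D (25OHD) — against each other as risk factors for a
disease such as multiple sclerosis / clinically isolated syndrome (MS/CIS).
It is aimed at analysts of matched case-control studies who need to:

* reconstruct **cumulative lifetime UVR dose** (kJ/m²) from residence
  histories, leisure-time-outdoors behaviour and a monthly
  latitude-by-month climatology, from age 6 to the index date, plus the
  recent summer/winter doses of the final 12 months;
* **deseasonalize** a single serum 25OHD draw, either by regression
  residuals (season of draw + BMI) or by a seasonal polynomial fitted in
  controls only, with clinical threshold (30/50/75 nmol/L) and quintile
  codings;
* estimate **mutually adjusted odds ratios** — both exposures in the same
  unconditional logistic model, adjusted for age, sex, smoking, genetic
  ancestry and HLA-DRB1\*15:01 — and **matched odds ratios** by conditional
  logistic regression over case-control sets;
* compare case and control characteristics with the standard descriptive
  battery (Welch t, χ², Fisher exact, Wilcoxon-Mann-Whitney);
* validate all of the above against a **synthetic matched-cohort
  generator** with configurable race/ethnicity-specific effects.

## The models at the core

Cumulative dose for participant $i$ sums behaviour-weighted ambient UVR
over calendar months $m$ from age 6 to the index date $T_i$:

$$D_i = \sum_{m} A(\ell_i(m), \mathrm{moy}(m)) \, w_i(m) \, f_m
\qquad \text{(kJ/m}^2\text{, modelled per 1000 kJ/m}^2)$$

with $A$ the climatology (linearly interpolated in latitude), $w_i$ the
outdoors weight in force, and $f_m$ the day-count proration of boundary
months.  Disease odds are modelled per group $g$ as

$$\operatorname{logit} P(\text{case}) = \alpha +
\beta_{\mathrm{UVR}} D_i/1000 + \beta_{\mathrm{VD}} \log \widetilde{V}_i +
\gamma' z_i,$$

where $\widetilde V_i$ is deseasonalized 25OHD and $z_i$ the adjustment
covariates; matched analyses maximise the conditional likelihood
$\prod_s e^{x_{case}\beta} / \sum_{m\in s} e^{x_m\beta}$.  Both likelihoods
are maximised by in-package Newton/IRLS fitters with step-halving,
separation detection and Wald odds-ratio inference
(`fit_logistic()`, `fit_conditional_logistic()`, `wald_or()`).

## Worked example

Simulate a three-group matched cohort under the package's default study
conditions (true UVR odds ratios 0.53 / 0.66 / 0.68 per 1000 kJ/m² in
blacks / hispanics / whites; a true 25OHD effect of 0.52 per log-unit in
whites only), then run the mutually adjusted analysis:

```r
library(helioepi)

cfg    <- sim_config(n_cases_per_group = 500, seed = 20180227)
bundle <- generate_cohort(cfg)
bundle
#> matched case-control cohort bundle
#>            case control
#>   black     500     500
#>   hispanic  500     500
#>   white     500     500

clim <- default_climatology()
expo <- exposure_summary(bundle$participants, bundle$residences,
                         bundle$outdoors, clim)
adj  <- do.call(rbind, lapply(cfg$groups, function(g) {
  ids <- bundle$participants$id[bundle$participants$group == g]
  deseasonalize_residual(bundle$serum[bundle$serum$participant_id %in% ids, ])
}))
ors <- do.call(rbind, lapply(cfg$groups, function(g)
  mutual_adjustment_analysis(bundle$participants, expo, adj, g)))
ors[, c("group", "term", "odds_ratio", "ci_low", "ci_high", "p_value")]
#>      group     term odds_ratio ci_low ci_high  p_value
#> 1    black uvr_1000      0.518  0.427   0.629 2.50e-11
#> 2    black log_vitd      0.676  0.440   1.040 7.50e-02
#> 3 hispanic uvr_1000      0.733  0.596   0.902 3.37e-03
#> 4 hispanic log_vitd      0.903  0.593   1.377 6.36e-01
#> 5    white uvr_1000      0.598  0.494   0.723 1.06e-07
#> 6    white log_vitd      0.581  0.383   0.884 1.11e-02
```

Each row is an adjusted odds ratio with its 95% Wald interval: at n = 500
pairs per group the UVR estimates already sit near their generating values
(protective in every group), while the 25OHD interval excludes 1 only in
the group generated with a true vitamin D effect.  `run_pipeline()` wraps
the same chain — simulate (or load CSV tables), reconstruct exposure,
deseasonalize, fit, tabulate — writing each stage as CSV plus a JSON
manifest, and `inst/cli/helioepi` exposes it as
`simulate` / `exposure` / `deseason` / `fit` / `table1` / `run`
subcommands.

See the methods vignette (`vignettes/methods.Rmd`) for the dose model,
the two deseasonalization procedures, the generator's assumptions and the
package's numerical choices.

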