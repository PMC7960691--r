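---
title: "Methods: severity-split hearing loss estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity-split hearing loss estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hearburden` re-implements, at desk scale, the estimation chain used in
global burden-of-disease style analyses of bilateral hearing loss: noisy,
heterogeneous survey inputs are harmonised to a reference case definition,
smoothed into severity-specific prevalence surfaces with full uncertainty
propagation, split into health states, converted to years lived with
disability (YLDs), and forecast forward. This vignette documents the model
assumptions, the main tuning parameters and their defaults, the scope of the
synthetic data generator, and the package's numerical conventions.

## Severity scheme and disability weights

Hearing loss is categorised by the better-ear pure-tone average (PTA) over
0.5, 1, 2 and 4 kHz into seven categories on half-open decibel intervals
`[db_low, db_high)`:

| category          | dB range  |
|-------------------|-----------|
| normal            | [0, 20)   |
| mild              | [20, 35)  |
| moderate          | [35, 50)  |
| moderately severe | [50, 65)  |
| severe            | [65, 80)  |
| profound          | [80, 95)  |
| complete          | [95, Inf) |

The half-open convention means a threshold value such as exactly 35 dB
belongs to the higher category; `classify_threshold()` implements this and
`severity_scheme()` returns the table. Each non-normal category maps to two
health states — with and without co-occurring tinnitus ("ringing") — whose
disability weights are frozen constants shipped in
`inst/extdata/disability_weights.tsv` and accessed via
`disability_weights()` and `lookup_weight()`. Normal hearing has weight 0
and is never split by tinnitus.

## Uncertainty representation: the `draw_surface`

All estimated quantities are carried as a `draw_surface`: a keys tibble
(location, year, sex, age group, and optionally category/cause) paired with
a cells × draws matrix. Arithmetic is done draw-wise, so correlations
between quantities computed from the same fit are preserved through every
downstream transformation. Summaries (`ds_summary()`, `summarize_draws()`)
report the mean and a 95% uncertainty interval (UI) taken as the
nearest-rank 2.5th and 97.5th percentiles: with `D` draws, the
`ceiling(0.025 D)`-th and `ceiling(0.975 D)`-th order statistics (draws
25 and 975 of 1000). The default draw count is 1000; smaller counts trade
interval stability for speed and are used in the examples below.

## Data processing

Raw survey rows may be reported for both sexes combined, for non-reference
dB thresholds, or for wide age spans. `process_survey_data()` harmonises
them in a fixed order; each step conserves implied case counts.

* **Sex splitting** (`fit_sex_ratio()`, `apply_sex_split()`). Studies
  reporting both sexes together are split using female:male ratios
  meta-analysed per age group from studies that report both sexes, on the
  log scale, with 10% trimming of extreme ratios and inverse-variance
  random-effects pooling; ages with too few pairs fall back to the pooled
  ratio. The split solves the ratio constraint jointly with conservation of
  the population-weighted mean, and deflates effective sample sizes by the
  population shares.
* **Threshold crosswalk** (`fit_crosswalk()`, `apply_crosswalk()`).
  Non-reference dB ranges are mapped to the reference definition via the
  mean logit difference estimated from microdata cells tabulated under both
  definitions, applied as a logit shift. Zero or full cells use a half-case
  continuity correction `(x + 0.5) / (n + 1)`.
* **Age splitting** (`age_split()`). Rows spanning more than 20 years of
  age are split into 5-year groups proportionally to a reference age
  pattern, conserving the implied cases of the original row.

## Prevalence model and squeezes

`fit_category_model()` is the meta-regression surrogate: per sex, a
quasibinomial GAM (`mgcv::gam`) on the logit scale with a penalised
thin-plate spline over age mid-points, optional covariates with sign
constraints (a violating covariate is dropped and the model refitted),
location random intercepts, and effective sample sizes as weights,
estimated by REML. Three mechanisms make the intervals honest about more
than sampling noise:

1. the quasibinomial Pearson dispersion inflates coefficient uncertainty;
2. coefficient draws come from the multivariate normal approximation with
   smoothing-parameter uncertainty included (`vcov(unconditional = TRUE)`);
3. a method-of-moments between-cell heterogeneity τ — the variance of
   observed logits around the fitted surface net of binomial sampling
   variance — is added as independent logit-scale noise to the prediction
   draws. This yields *predictive* intervals: when the additive
   age + location model family cannot represent the true surface, τ > 0
   and the UIs widen accordingly; when the family is correct, τ ≈ 0 and
   nothing changes.

`model_config()` defaults: `df = 8` spline basis functions (enough for a
smooth age profile over ~20 age groups while letting REML penalise excess
wiggliness), covariate `"sdi"` (the development index of the synthetic
world), location random intercepts, 1000 draws.

Eight surfaces are fitted — normal, mild, moderate-plus, and the five
severities at 35 dB and above — then reconciled by two squeezes applied per
cell and per draw:

* `squeeze_top_level()` rescales normal, mild and moderate-plus by their
  three-way sum so the top-level categories sum to exactly 1;
* `squeeze_severities()` rescales the five severity surfaces to the
  moderate-plus envelope. Cells where all five sub-models are zero but the
  envelope is positive are filled using the sub-models' global mean shares,
  with a warning.

## Hearing aids, causes, tinnitus

* **Hearing aids.** `fit_coverage()` models aided proportions per severity
  with the same GAM machinery; a per-draw running maximum enforces that
  coverage is non-decreasing in severity, and severities with no data
  borrow the adjacent estimate. `apply_aid_shift()` moves the aided
  fraction of each category one severity category down, simultaneously
  across categories (no cascading), conserving total prevalence; an
  attribute guards against double application.
* **Causes.** `attribute_causes()` splits each severity's prevalence among
  congenital, otitis media, meningitis and age-related/other causes. Under
  age 20 the modelled causes are proportionally squeezed to the envelope;
  at 20+ the age-related/other cause is the residual after the specific
  causes, with a proportional rescale (and warning) if the specific causes
  exceed the envelope. Attribution is additive by construction.
* **Tinnitus.** `estimate_tinnitus()` estimates the proportion of each
  severity stratum with co-occurring tinnitus from microdata, climbing a
  pooling ladder (stratum → pooled sexes → widening age windows → severity
  → overall) until enough respondents are found. `split_by_tinnitus()`
  splits each severity surface into the two health states with a
  truncated-normal draw of the proportion per posterior draw; the two
  states sum exactly to the input.

## Burden, comparisons, forecasting

`compute_ylds()` multiplies health-state prevalence by the disability
weights — optionally sampling weight uncertainty from the published
intervals — so a unit-prevalence cell's YLD rate equals the weight itself.
`aggregate_burden()` sums locations to regions and the global total;
`age_standardize()` applies a fixed age-weight vector to rates.
`percent_change()` follows the draw-level convention: change is computed
within each draw and then summarised, so the reported mean change is the
mean of per-draw changes, not the change of means. `haq_regression()`
regresses location-level unmet need on the access-and-quality index.
`fit_forecast()`/`project()` fit, per sex, a linear model of logit rates on
region × calendar-year interactions and a cubic B-spline in age (knots at
the age quintiles), extrapolate to future years, add residual bootstrap
noise, and convert to counts with the projected populations.

## Synthetic world generator: scope and limits

`make_truth()` builds a fully known world: a location hierarchy with a
development index, log-linear population growth with ageing, a logistic
age–sex–development model for moderate-plus prevalence with location
random effects, a conditional model for mild loss, within-band dB
distributions, cause fractions with an age-related share rising in age,
severity-dependent tinnitus co-occurrence, and hearing-aid coverage rising
with severity and development. `simulate_microdata()` draws individual
respondents; `tabulate_survey()`/`tabulate_coverage()` aggregate them into
survey-like rows, including deliberately awkward ones (both-sex rows,
non-reference thresholds, wide age spans) for the processing pipeline to
repair.

The generator is a caricature, not an epidemiological model: causes are
assigned independently of severity given age, tinnitus is independent of
everything but severity, and there are no cohort or period effects beyond
a smooth year trend. It exists to give the estimation chain a ground truth
whose recovery can be tested, not to describe any real population.

## End-to-end run

```{r}
library(hearburden)
config <- pipeline_config(
  truth = truth_config(),  # 6 regions x 3 locations, 7 estimation years
  seed = 1L,
  n_per_stratum = 500L,    # survey respondents per location-year-sex-age cell
  n_draws = 200L           # posterior draws
)
manifest <- run_pipeline(config)
manifest$summaries$all_loss_prevalence_pct_2019
report <- report_severity_table(manifest)
```

`run_pipeline()` executes every stage in order, logs each stage with a
checksum, and returns a manifest of surfaces, summary quantities and the
regional severity report. The defaults above run in a few minutes on one
CPU; `n_per_stratum` and `n_draws` are the levers that trade precision for
time.

## Numerical conventions and limitations

* Age groups are 5-year bands keyed by their lower bound; age mid-points
  are used in all smooth models.
* Conservation identities (squeezes, splits, aid shift, attribution) hold
  to machine precision and are enforced by the test suite.
* All randomness flows from user-supplied seeds through local RNG scopes;
  identical configurations give byte-identical outputs.
* Limitations: no remission or mortality dynamics (pure prevalence
  arithmetic); the forecast is a trend extrapolation without demographic
  feedback; the crosswalk assumes a constant logit offset across ages;
  uncertainty from the sex-split and age-split steps is carried through
  effective sample sizes rather than explicit draws.
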