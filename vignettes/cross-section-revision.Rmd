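---
title: "Revising MELD-type scores from calendar-time cross-sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Revising MELD-type scores from calendar-time cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Liver transplant candidates are prioritized by MELD-type scores — affine
functions of the logs of serum creatinine, bilirubin and the INR — that
are meant to rank candidates by 90-day waitlist mortality risk.
Historically such scores have been re-estimated "from registration":
a 90-day time-stopped Cox model is fitted from each patient's listing
date using the biomarkers reported at listing, censoring at
transplantation or delisting.  That design discards every biomarker
report made after listing and every death occurring more than 90 days
after listing, and it treats transplantation as non-informative
censoring even though sicker patients are transplanted sooner.

`dynmeld` implements the alternative "from cross-section" design: a grid
of pre-specified calendar dates is laid over the registry; at each
cross-section every actively listed, transplantable patient contributes
one observation whose covariates are the *last biomarkers reported on or
before* that date and whose outcome is 90-day time-stopped survival
*from* that date.  The Cox model is stratified by country and
cross-section, with time since cross-section as the time scale, so
patients waiting a long time contribute many (correlated) observations
and late deaths inform the fit.  Dependent censoring by transplantation
and delisting is addressed with inverse probability of censoring
weighting (IPCW): cause-specific extended Cox models for transplantation
(IPCW-T) and delisting (IPCW-D) with time-varying reported covariates
yield, for each analysis row, the probability of remaining free of both
censoring causes along its realized covariate history, and rows are
weighted by the inverse of that probability (the product form assumes
the two causes are conditionally independent given the covariates).

## Outcome definition

Waitlist death within 90 days of the time origin is the event.  A
delisted patient who dies within 90 days of deregistration is treated as
having died at waitlist exit; other delistings, transplantations, the
90-day horizon and the administrative data cutoff censor.  Delisted
patients with less than 90 days of post-delisting follow-up and no
recorded death are censored at exit (a conservative choice; the counts
appear in the exclusion report).

## The model pipeline

`run_pipeline()` wires the stages together: simulate or read a registry;
validate it (episodes with impossible biomarker reports, e.g. the
all-zero artifact, are excluded); split it into development and
validation cohorts by *center* so that validation is geographical
(single-center countries are split at random); build the
from-registration and from-cross-section datasets; fit the censoring
models and weights on the development cohort; fit the three Table-style
mortality models (reference-score offset, refit without IPCW, refit with
IPCW); rescale the IPCW cross-section fit to the MELD point scale by
quantile matching; and evaluate the derived score against UNOS-MELD and
ReMELD with a time-truncated concordance index and per-score 90-day risk
tables.

Some estimation choices deserve comment.

**Ties and time granularity.**  Registry dates are whole days, so event
times are heavily tied; all partial likelihoods use Efron's tie
correction.

**Cluster-robust standard errors.**  A patient active at many weekly
cross-sections contributes many rows whose 90-day windows overlap.
Model-based standard errors treat those rows as independent and are
anti-conservative; `fit_mortality_model()` therefore also reports
standard errors from the patient-clustered robust (sandwich) variance,
and those are the ones used for inference and for the parameter-recovery
checks in the test suite.

**Censoring-model covariates.**  Transplant offers are driven by the
allocation score, so the censoring models default to the
allocation-scale transforms (UNOS-capped log biomarkers with the
dialysis creatinine substitution) plus the dialysis flag; raw-log
covariates and covariates frozen at the cross-section are options.
Censoring models are stratified by country but pooled over
cross-sections, otherwise weekly strata would leave most strata without
transplant events.

**Weight construction.**  Weights are step functions along follow-up,
rebuilt at every post-cross-section report.  Because a row at risk at an
event time inside one of its intervals would otherwise carry the
interval-end weight — an excess of up to the interval's censoring-hazard
increment, differentially by severity — intervals are subdivided so no
piece accumulates more than `max_hazard_step = 0.02` joint censoring
cumulative hazard (1-day pieces make the weight exact on the day grid;
the default is a compromise between exactness and fitting cost).
Stabilization by the marginal per-country censoring survival is on by
default and weights are truncated at their 99th percentile; both are
switches, so the plain unstabilized estimator can be run.

**Offset fits.**  Comparing a new fit against an existing score requires
the score's points on the log-hazard scale.  The offset is
`points / a`, where the scale `a` is either supplied or estimated by
quantile-matching the offset score against the linear predictor of the
no-offset fit on the same rows.  A mis-scaled offset distorts the
likelihood-ratio test, which is why the scale is explicit and the
type-I-error simulation in the test suite supplies the known scale.

**Cap search.**  Biomarker caps are chosen by maximizing the fitted
log partial likelihood over a per-biomarker grid of (lower, upper)
pairs, coordinate-wise in the order creatinine, bilirubin, INR, sweeping
at most three times, with ties broken toward wider bounds.  A joint grid
would be combinatorial and the one-dimensional profiles are nearly
separable in practice.

**Quantile matching.**  The fitted linear predictor is mapped to the
MELD point scale by regressing reference-score percentiles (1–99) on
linear-predictor percentiles.  The derived score's coefficients are
rounded to two decimals only at this final step; the dialysis
coefficient is dropped in favor of the clinical substitution rule
"creatinine = upper cap under dialysis", which is justified when the
dialysis-equivalent creatinine `exp(beta_dialysis / beta_creatinine)` is
close to the upper cap.

**Concordance.**  Discrimination is measured by a time-truncated,
inverse-probability-weighted c-index: over pairs with an observed event
before the earlier of the partner's time and the horizon, concordance is
credited when the dying patient carried the higher score (half credit on
ties), with pair weight `1/G(t_i)^2` where `G` is by default the
Kaplan–Meier of the pooled censoring process; a model-based
`S_T * S_D` given each row's cross-section covariates is the
dependent-censoring option.  Score comparisons bootstrap *patients*
(all rows move together) because cross-section rows repeat patients.

**Absolute risks.**  Per-score 90-day risks come from a Cox model on the
rounded integer score with a Breslow baseline, fitted on rows
deduplicated to each reported biomarker set's first active
cross-section, with and without IPCW; a Kaplan–Meier estimate at each
patient's first reach of a score serves as a proportional-hazards-free
check.

## The synthetic registry generator

Real waitlist registries of this kind are not publicly accessible, so
the package ships a generator (`simulate_registry()`) that reproduces
the *dependence structure* the analysis relies on, with known ground
truth — not any real registry's marginal distributions.

* Latent log-biomarkers follow a day-granular random walk.  A
  "progressor" subgroup (30%) drifts upward (bilirubin doubling in
  about a year); day-to-day volatility is about 1% per day at
  UNOS-MELD 20 and increases with current severity
  (`exp(0.03 * (score - 20))` per point) — sicker cirrhotic patients'
  laboratory values are more labile, which is also why Eurotransplant
  requires 7-day recertification above MELD 25.
* Reports are emitted at registration, whenever the current report's
  age exceeds the recertification limit for the patient's reported
  score band (365 / 90 / 30 / 7 days for bands <10 / 10–18 / 19–24 /
  ≥25; the extremes follow the published Eurotransplant rule, the
  middle bands are interpolated), plus rare voluntary updates.
* The death hazard each day is log-linear in the currently *reported*
  covariates, with default coefficients (2.15, 0.97, 2.22, dialysis
  1.86) — the published cross-section IPCW fit.  Using reported rather
  than latent values keeps a censoring model with time-varying reported
  covariates correctly specified.
* Transplant and delisting hazards are constant (scenario
  `A_independent`) or log-linear in the currently reported UNOS-MELD
  score (scenario `B_informative`).  Hazard levels and gradients were
  calibrated once against the published per-band 90-day event
  fractions (transplant rising from ~6% below MELD 15 to ~45% above
  25; overall from-cross-section death fraction near 8%), and most
  dialysis is prevalent at listing with a small incident rate.
* Delisted patients' death process continues for 90 days with hazards
  frozen at delisting values; deaths there feed the reclassification
  rule.  NT (non-transplantable) intervals are inserted for 5% of
  patients and affect cross-section eligibility only.
* Competing events within a day are resolved by total-hazard draw and
  cause selection proportional to the cause hazards, which is the exact
  competing-exponentials resolution within a constant-hazard day.

What the generator does *not* emulate: real marginal biomarker
distributions and correlations, exception points, re-transplantations,
center-level practice variation beyond random center sizes, and any
terminal acceleration of biomarkers beyond the severity-dependent
volatility.  Passing tests therefore demonstrate correctness of the
estimators under the stated dependence structure, not performance on
real registry data.

Two consequences of this structure are worth stating plainly, because
the test suite documents them.  First, with censoring hazards that are
exponential in the reported score and near-Gaussian covariate evolution,
the selection exerted by censoring tilts post-cross-section evolution by
almost the same amount at every covariate level, so the *coefficients*
of the naive from-cross-section fit are only mildly biased and the IPCW
correction to them is small — consistent with the published finding that
IPCW moved coefficients by less than a standard error.  Second, the
IPCW effect on *absolute risks* in this generator is likewise small and
need not be an inflation at every score: the delisting-death
reclassification moves score-selected delisting deaths to their exit
date, a feature of the outcome definition that weighting does not undo.
The large risk inflation reported on real data requires transplant
selection on prognosis beyond the adjusted score, which the generator's
score-driven allocation deliberately does not contain.

## Problem sizes used by the tests

Parameter-recovery checks run 20 replicate registries of 3,000 patients
over a two-year window with weekly cross-sections (roughly 60,000
analysis rows each); the offset type-I-error check runs 400 replicates
of 800 single-stratum rows; the qualitative event-rate checks use one
registry of 5,000 patients.  These sizes give Monte-Carlo error well
below the tolerances being asserted while keeping the default test run
in the minutes range.

## Numerical and degenerate-input conventions

Dates are whole days and all durations integer days.  "Before the
cross-section date" is implemented inclusively (a report dated on the
cross-section day is usable — allocation that day would use it);
exclusive is a switch.  A patient whose exit date equals the
cross-section date is not active (half-open interval).  Same-day
duplicate reports resolve to the last ingested.  Strata without events
drop out of partial likelihoods with a count kept.  Zero-variance
linear predictors, all-zero biomarker reports, missing censoring-cause
events, and negative LR statistics raise errors rather than propagate.
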