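---
title: "Methods: episode reconstruction, cascade staging and stage-membership models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: episode reconstruction, cascade staging and stage-membership models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oatcascade)
```

## The problem

Opioid agonist treatment (OAT) with methadone or buprenorphine/naloxone is
the standard maintenance pharmacotherapy for opioid use disorder, and the
benefit of treatment accrues with retention. A *cascade of care* summarises a
treated population by how far along the engagement continuum each patient
gets. `oatcascade` operationalises a four-stage retention cascade over
longitudinal clinic dosing records: it reconstructs treatment episodes from
raw dose dates, classifies each patient by their longest episode, derives the
standard descriptive covariates, and models stage membership with a
baseline-category multinomial logit.

## Episode reconstruction

The unit of analysis is the **treatment episode** (equivalently, treatment
window): a maximal run of dosing not interrupted by a disqualifying dose-free
gap. The gap is medication-specific — **5 days without a methadone dose, 6
days without a buprenorphine/naloxone dose** — reflecting clinical guidance
that a patient absent for that long must be re-inducted on starting doses.

Numerical conventions, chosen once and applied everywhere:

* Dates are whole calendar days; there is no time-of-day.
* "N days without a dose" means a run of at least N whole dose-free days
  between two dose dates, i.e. an episode splits exactly when
  `next_date - last_date >= gap + 1`. Doses on days 0–10 and day 15
  (4 dose-free days) remain one methadone episode; days 0–10 and day 16
  (5 dose-free days) split into two.
* `duration_days` is inclusive of both endpoints (`end - start + 1`); a
  single-dose episode has duration 1, so no episode has length zero and
  retention is measured in days *in* treatment.
* When methadone and buprenorphine records interleave, the applicable gap
  after any dose is that of the most recently dosed medication — the clock
  that matters clinically is "days since the last dose of the drug the
  patient was last on". If both medications were dosed on the same last day,
  the larger (more permissive) gap applies; this tie cannot change results
  under the default rule unless records genuinely interleave within a day.
* An episode's medication is that of its first dose. Medication switches
  within an episode do not split it and are not otherwise tracked; the
  patient's starting medication is the medication of their first episode's
  first dose.
* Duplicate `(patient, date, medication)` rows collapse to one record keeping
  the maximum dose, with a warning count. Doses after the study close are
  dropped with a warning and episodes are right-truncated there.

A patient's history then summarises to: number of **treatment attempts**
(= number of episodes), **longest retention** (the longest single episode —
not the cumulative total across episodes, matching how per-patient retention
is reported descriptively), first initiation date, and **administrative loss
to follow-up** (last episode ends strictly before the study close with no
later episode; ending exactly at the close does not count as lost).

The reconstruction is verified two ways: against a brute-force day-scan
oracle (an independent implementation that walks every calendar day and
splits on any dose-free run reaching the gap) on thousands of random small
histories, and by exact round-trip recovery of planted episodes from the
synthetic generator.

## Cascade staging

Longest retention maps to four stages. The verbal stage labels ("less than
90 days", "90 to 365 days", "one to two years", "more than 2 years") overlap
at their printed boundaries, so the package fixes the partition

* `LT_90`: `[0, 90)` days
* `D90_365`: `[90, 365]`
* `Y1_2`: `(365, 730]`
* `GT_2Y`: `(730, Inf)`

with one year = 365 days, two years = 730, leap days ignored. This is the
simplest convention consistent with "less than 90 days" and "more than 2
years" that makes the four stages a true partition. Cascade tables are
tabulated by calendar year of *first* initiation (a patient re-engaging in a
later year stays in their first-initiation year) and by geographic region;
patients with missing geography are excluded from the regional tables and
reported as an exclusion count, never silently dropped. Display percentages
round half-up (integer percent for the yearly cascade, one decimal in
characteristics tables).

## Covariates

* **UDS quadrants.** For each of five drug classes (amphetamine-type
  stimulant, fentanyl, cocaine, cannabis, other opioid — the class labels
  already exclude the patient's own OAT medication and fentanyl from "other
  opioid"), the proportion of positive urine drug screens over all of the
  patient's tests in the study window is binned into quarter bins
  `(-Inf, .25]`, `(.25, .5]`, `(.5, .75]`, `(.75, 1]`. The closed-left
  placement makes the bins exhaustive and mutually exclusive and sends a 26%
  positivity to the second bin, as the percent labels read. Patients with no
  tests of a class sit at proportion 0 (first quadrant) and carry an
  explicit `any_uds` flag, since the reporting layout has no "untested"
  category.
* **Average monthly UDS.** Screening *events* are distinct
  `(patient, date)` pairs — one clinic visit is one event however many
  classes the assay panel reports. The monthly rate is total events divided
  by total days in treatment (sum of episode durations) at 30.4375
  days/month (365.25/12). "Monthly" is not otherwise defined in the field's
  reports; this denominator is reproducible and insensitive to calendar
  alignment.
* **Region.** Northern means health-region (LHIN) code 13 or 14; rural means
  a Rurality Index of Ontario (RIO) score of 40 or higher; crossed they give
  the four strata. Real postal-code geocoding is out of scope — a small,
  clearly synthetic postal-prefix lookup ships only to exercise the
  interface.
* **Age groups** `<25`, `25–45`, `46–65`, `65+` at first initiation, from
  birth year when age is not given directly. The printed labels place 65 in
  two groups; the package assigns exactly-65 to `46–65` and floors
  fractional ages to completed years.
* **Dose indicators.** Starting dose is the first record of episode 1; peak
  is the maximum over all the patient's records of their starting
  medication. Cohort medians of the *peak* dose are computed per medication,
  and both `start_above_median` and `peak_above_median` compare strictly
  (`>`) against that median peak — reading the indicator label "start dose
  above-median peak dose" literally. In a one-patient cohort the patient's
  peak equals the median and both indicators are `FALSE`.

## Stage-membership models

The response is the four-stage factor with `LT_90` as the reference; the
model is the baseline-category (multinomial) logit. Odds ratios are
`exp(coefficient)` with Wald intervals at `z = qnorm(0.975)` — Wald rather
than profile-likelihood, matching the symmetric intervals conventionally
printed in cohort tables.

* **Crude** means one single-covariate model per covariate (standard
  epidemiological usage); **adjusted** puts all declared covariates in one
  model. Rows missing any modelled covariate are dropped complete-case and
  counted.
* The fitter is a full Newton–Raphson maximiser of the multinomial
  log-likelihood with step-halving, so the log-likelihood is nondecreasing
  across iterations; convergence is a relative log-likelihood change below
  `1e-8`; there is no penalty, and separation surfaces as an explicit
  non-convergence status (diverging coefficients or a singular Hessian),
  never as silently clipped estimates.
* Two independent routes guard the estimates: for a single categorical
  covariate the model is saturated, so fitted ORs must equal the closed-form
  contingency cross-product ratios to `1e-6` relative (this identity is an
  exported oracle, `crude_or_from_counts()`), and the test suite also
  cross-checks a mixed-covariate fit against `nnet::multinom`.
* Relabelling the reference stage transforms ORs by the identity
  `OR'_s = OR_s / OR_{s'}`; this invariance is tested.

The characteristics report uses a chi-square test of independence for
categorical covariates and one-way ANOVA across the four stages for
continuous ones, with ORs and CI bounds displayed to 2 decimals, half-up.

## The synthetic EMR generator

Clinic EMR extracts of this kind cannot be redistributed, so the package
ships a seeded generator whose output has *known ground truth*: planted
episodes (starts, ends, medication), the implied stage, region, and
configured UDS positivity per class. Every downstream stage then has an
exact recovery test rather than a plausibility check.

Defaults encode the study conditions the pipeline targets: a 2014–2020
window; 77.6% methadone starts; sex mix 61.4% M / 38.5% F with a 0.1%
missing sliver; age Normal(35.6, 10.7) truncated at 18; region mix 4.3%
Northern rural, 17.9% Northern urban, 3.4% Southern rural, 74.4% Southern
urban; about 6.05 UDS events per treatment month. Where the field's reports
state no value, the generator fixes one plausible choice and does not treat
it as a tuning dial: episode lengths lognormal(meanlog = log 365,
sdlog = 1.5) (median one year, heavy right tail — chosen to spread patients
over all four stages), inter-episode gaps of rule-minimum plus a
geometric(mean 60) extra, target attempts 1 + Poisson(1.17) (mean 2.17),
within-episode dose-miss probability 0.15, and linear dose ramps (methadone
30→80 mg, buprenorphine 8→16 mg over 30 days) in place of any real
titration pharmacology.

Two structural guarantees make recovery exact by construction:
inter-episode gap draws are clamped to at least the disqualifying gap of the
episode's medication, and within-episode runs of missed days are forced
strictly below it (a dose is inserted on every gap-th missed day; first and
last episode days are always dosed). All randomness flows from one seed per
call via an RNG scope that leaves the global state untouched, so identical
configurations are byte-identical on re-run.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: medication switching within patients,
dose titration dynamics, informative missingness of UDS scheduling (real
take-home schedules tie screening frequency to negative screens),
postal-code geography, or correlation between covariates and retention
beyond what `generate_stage_odds_cohort()` plants explicitly. The second
generator draws stage labels directly from a specified multinomial logit
over independent Bernoulli(0.5) covariates, and exists purely for parameter
recovery and CI-coverage testing of the model code.

## Problem sizes and runtime choices

The test suite verifies the builder-oracle agreement on 1,300 random
histories, exact round-trip recovery at 2,000 patients, OR recovery at
n = 50,000, and Wald coverage over 200 replicates of n = 5,000 — sizes at
which the binomial error bands are tight enough to be informative while the
whole suite stays comfortably interactive (about a minute). The pipeline
smoke tests run at a few hundred patients, where the adjusted model (about
60 free parameters) is still well-conditioned.

## Known limitations

* Whether ongoing treatment begun before the window start should be
  left-truncated is data-dependent; the builder exposes truncation at the
  close (`study_end`) and leaves the start boundary to the caller.
* Longest-episode retention understates cumulative time in treatment for
  patients who cycle; the attempts count partially captures this.
* Complete-case handling of missing covariates assumes missingness
  unrelated to stage; no imputation is provided.
* The crude/adjusted distinction follows standard usage; with strongly
  correlated covariates (attempts, UDS frequency, dose indicators) adjusted
  estimates can differ in sign from crude ones — that is expected behaviour,
  not a defect.
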