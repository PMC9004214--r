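# oatcascade

Cascade-of-care analysis for opioid agonist treatment (OAT) records.

## What it does, and for whom

Clinics treating opioid use disorder with methadone or buprenorphine/naloxone
accumulate longitudinal dosing logs, urine drug screen (UDS) results and
demographics in their EMRs. Analysts studying treatment retention need to
turn those raw tables into the standard epidemiological outputs: treatment
episodes, a retention **cascade of care**, descriptive covariates, and odds
ratios of stage membership. `oatcascade` is that pipeline, as a tested R
package:

1. **Episode reconstruction** — a treatment episode is a maximal run of
   dosing with no disqualifying dose-free gap: **5 days without a methadone
   dose, 6 days without a buprenorphine/naloxone dose** ends an episode
   (patients absent that long are clinically re-inducted on starting doses).
   Episodes yield per-patient treatment attempts, longest retention and
   administrative loss to follow-up.
2. **Cascade staging** — longest retention `d` maps to four stages:
   `LT_90` (`d < 90`), `D90_365` (`90 ≤ d ≤ 365`), `Y1_2`
   (`365 < d ≤ 730`), `GT_2Y` (`d > 730`); tabulated by initiation year and
   by the four Ontario-style geography strata (Northern/Southern ×
   rural/urban; Northern = health region 13–14, rural = RIO score ≥ 40).
3. **Covariates** — UDS positivity quadrants per drug class
   (`≤25%, 26–50%, 51–75%, 76–100%`), average monthly UDS at 30.4375
   days/month, age groups, and above-median dose indicators.
4. **Multinomial models** — crude and adjusted baseline-category logits of
   stage (reference `LT_90`). For stage *s* and covariate vector *x*:

   log [ Pr(stage = s) / Pr(stage = LT_90) ] = x' β_s ,  s ∈ {D90_365, Y1_2, GT_2Y}

   fitted by Newton–Raphson with step-halving; OR = exp(β) with Wald 95% CIs.
   A closed-form contingency oracle (`crude_or_from_counts()`) provides an
   independent check: for one categorical covariate the fitted model is
   saturated and must agree to 1e-6 relative.
5. **Synthetic EMR generator** — seeded cohorts with known planted episodes,
   stages, regions and UDS positivity, so every stage of the pipeline has an
   exact recovery test (real extracts of this kind are not shareable).

`run_pipeline()` orchestrates the whole flow (simulate or ingest CSVs →
episodes → summaries → cascade tables → models) and writes CSV artifacts
plus a JSON manifest with an explicit exclusion ledger.

## Worked example

```r
library(oatcascade)

cfg <- cohort_config(n_patients = 300, seed = 2024)
cohort <- generate_cohort(cfg)
episodes <- build_episode_table(cohort$doses, cfg$gap_rule, study_end = cfg$study_end)
histories <- summarize_histories(episodes, cfg$study_end)
summaries <- build_patient_summaries(histories, cohort$uds, cohort$patients,
                                     cohort$doses, episodes)
dplyr::count(summaries, stage)
#> # A tibble: 4 × 2
#>   stage       n
#>   <fct>   <int>
#> 1 LT_90      22
#> 2 D90_365    90
#> 3 Y1_2       82
#> 4 GT_2Y     106

head(cascade_by_year(histories), 4)
#> # A tibble: 4 × 5
#>   stratum stage   count total proportion
#>   <chr>   <fct>   <int> <int>      <dbl>
#> 1 2014    LT_90       2    43     0.0465
#> 2 2014    D90_365    10    43     0.233
#> 3 2014    Y1_2       10    43     0.233
#> 4 2014    GT_2Y      21    43     0.488
```

Of the 43 simulated patients first initiating in 2014, 48.8% were retained
more than two years; the `count`/`total` columns always conserve the
stratum total, and patients with missing geography are excluded from the
regional table with their count attached as `attr(, "n_excluded")`.

Crude odds ratios straight from a printed sex-by-stage contingency table
(male and `LT_90` as references):

```r
cnt <- rbind(M = c(3833, 4535, 3331, 8255),
             F = c(2227, 2707, 2080, 5485))
colnames(cnt) <- names(cascade_stages())
crude_or_from_counts(cnt)
#> # A tibble: 3 × 8
#>   level stage      or ci_low ci_high mode      n note
#>   <chr> <chr>   <dbl>  <dbl>   <dbl> <chr> <dbl> <chr>
#> 1 F     D90_365  1.03  0.957    1.10 crude 32453 <NA>
#> 2 F     Y1_2     1.07  0.996    1.16 crude 32453 <NA>
#> 3 F     GT_2Y    1.14  1.07     1.22 crude 32453 <NA>
```

Women in this cohort had 1.14 (95% CI 1.07–1.22) times the odds of men of
being retained over two years rather than under 90 days; fitting the same
data through `fit_multinomial(expand_counts(cnt), "level", mode = "crude")`
reproduces these values to numerical precision.

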