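test_that("UDS quadrants partition [0,1] with closed-left quarter bins", {
  expect_equal(as.character(uds_quadrant(c(0, 0.25))), c("Q0_25", "Q0_25"))
  expect_equal(as.character(uds_quadrant(0.2501)), "Q26_50")
  expect_equal(as.character(uds_quadrant(c(0.5, 0.5001, 0.75, 0.7501, 1))),
               c("Q26_50", "Q51_75", "Q51_75", "Q76_100", "Q76_100"))
  grid <- seq(0, 1, by = 0.001)
  q <- uds_quadrant(grid)
  expect_false(anyNA(q))
  expect_true(all(diff(as.integer(q)) >= 0))
  expect_error(uds_quadrant(1.01), "\\[0, 1\\]")
})

test_that("average monthly UDS uses the 30.4375 days/month convention", {
  expect_equal(avg_monthly_uds(0, 100), 0)
  expect_equal(avg_monthly_uds(12, 183), 12 / (183 / 30.4375))
  expect_equal(avg_monthly_uds(12, 183), 1.996, tolerance = 1e-3)
  expect_equal(avg_monthly_uds(6, 30), 6.0875)
  expect_error(avg_monthly_uds(1, 0), "at least 1")
})

test_that("region classification combines the RIO-40 and LHIN-13/14 rules", {
  expect_equal(as.character(classify_region(40, 13)), "Northern_rural")
  expect_equal(as.character(classify_region(39, 7)), "Southern_urban")
  expect_equal(as.character(classify_region(55, 7)), "Southern_rural")
  expect_equal(as.character(classify_region(10, 14)), "Northern_urban")
  expect_true(is.na(classify_region(NA, 7)))
  expect_true(is.na(classify_region(50, NA)))
  expect_error(classify_region(10, 15), "1\\.\\.14")
  # partition: every complete (rio, code) combination gets exactly one label
  grid <- expand.grid(rio = c(0, 39, 40, 90), code = 1:14)
  lab <- classify_region(grid$rio, grid$code)
  expect_false(anyNA(lab))
})

test_that("age groups partition ages with 65 in the 46-65 band", {
  expect_equal(as.character(age_group(c(24, 25, 45, 46, 65, 66))),
               c("<25", "25-45", "25-45", "46-65", "46-65", "65+"))
  expect_equal(as.character(age_group(45.9)), "25-45")  # completed years
  expect_false(anyNA(age_group(seq(0, 100, by = 0.5))))
  expect_error(age_group(-1), "nonnegative")
})

mk_cohort_doses <- function() {
  tibble::tibble(
    patient_id = c("a", "b", "b", "c", "c"),
    date = as.Date("2015-01-01") + c(0, 0, 1, 0, 1),
    medication = "methadone",
    dose_mg = c(40, 30, 80, 90, 120))
}

test_that("dose summaries compare against the cohort median peak dose, strictly", {
  doses <- mk_cohort_doses()
  eps <- build_episode_table(doses)
  ds <- dose_summaries(doses, eps)
  # peaks 40, 80, 120 -> median 80; patient c starts at 90 > 80
  expect_equal(unname(attr(ds, "median_peak")["methadone"]), 80)
  expect_true(ds$start_above_median[ds$patient_id == "c"])
  expect_false(ds$start_above_median[ds$patient_id == "b"])  # start 30
  expect_true(ds$peak_above_median[ds$patient_id == "c"])
  expect_false(ds$peak_above_median[ds$patient_id == "b"])   # peak == median

  # degenerate one-patient cohort: own peak equals the median, both FALSE
  one <- doses[doses$patient_id == "a", ]
  ds1 <- dose_summaries(one, build_episode_table(one))
  expect_false(ds1$start_above_median)
  expect_false(ds1$peak_above_median)

  # constant dosing: start equals peak
  expect_equal(ds$start_dose_mg[ds$patient_id == "a"],
               ds$peak_dose_mg[ds$patient_id == "a"])
})

test_that("dose medians are invariant to patient order", {
  doses <- mk_cohort_doses()
  eps <- build_episode_table(doses)
  ds1 <- dose_summaries(doses, eps)
  rev_doses <- doses[nrow(doses):1, ]
  ds2 <- dose_summaries(rev_doses, build_episode_table(rev_doses))
  expect_equal(attr(ds1, "median_peak"), attr(ds2, "median_peak"))
})

test_that("patients without UDS tests land in Q0_25 with an explicit flag", {
  doses <- mk_cohort_doses()
  eps <- build_episode_table(doses)
  hist <- summarize_histories(eps, as.Date("2015-12-31"))
  uds <- tibble::tibble(patient_id = "a", date = as.Date("2015-01-01"),
                        drug_class = c("cocaine", "cocaine", "fentanyl"),
                        result = c("positive", "positive", "negative"))
  us <- uds_summaries(uds, hist, eps)
  expect_false(us$any_uds[us$patient_id == "b"])
  expect_equal(as.character(us$uds_q_cocaine[us$patient_id == "b"]), "Q0_25")
  expect_equal(us$uds_n_cocaine[us$patient_id == "a"], 2L)
  expect_equal(us$uds_prop_cocaine[us$patient_id == "a"], 1)
  expect_equal(as.character(us$uds_q_cocaine[us$patient_id == "a"]), "Q76_100")
  # one clinic visit = one event regardless of assay classes
  expect_equal(us$n_uds_events[us$patient_id == "a"], 1L)
  expect_error(uds_summaries(dplyr::mutate(uds, drug_class = "nicotine"), hist, eps),
               "unknown drug_class")
})

test_that("patient summaries join all covariates and keep missing sex as a category", {
  doses <- mk_cohort_doses()
  eps <- build_episode_table(doses)
  hist <- summarize_histories(eps, as.Date("2015-12-31"))
  demo <- tibble::tibble(patient_id = c("a", "b", "c"),
                         sex = c("F", NA, "M"),
                         birth_year = c(1985, 1990, 1949),
                         rio_score = c(45, 10, NA),
                         health_region_code = c(13, 5, 2))
  uds <- tibble::tibble(patient_id = c("a", "zz"), date = as.Date("2015-01-02"),
                        drug_class = "cocaine", result = "negative")
  expect_warning(
    summ <- build_patient_summaries(hist, uds, demo, doses, eps),
    "not in dose records")
  expect_equal(nrow(summ), 3)
  expect_equal(as.character(summ$sex[summ$patient_id == "b"]), "missing")
  expect_equal(as.character(summ$region[summ$patient_id == "a"]), "Northern_rural")
  expect_true(is.na(summ$region[summ$patient_id == "c"]))
  expect_equal(summ$age[summ$patient_id == "a"], 30)
  expect_equal(as.character(summ$age_group[summ$patient_id == "c"]), "65+")
  expect_equal(as.character(summ$stage), as.character(classify_stage(summ$longest_retention_days)))
})

test_that("synthetic cohort quadrant frequencies track the configured positivity", {
  cfg <- cohort_config(n_patients = 120, seed = 55)
  coh <- generate_cohort(cfg)
  eps <- build_episode_table(coh$doses, cfg$gap_rule, study_end = cfg$study_end)
  hist <- summarize_histories(eps, cfg$study_end)
  us <- uds_summaries(coh$uds, hist, eps)
  for (cl in uds_drug_classes()) {
    n_tests <- sum(us[[paste0("uds_n_", cl)]])
    p_hat <- sum(us[[paste0("uds_prop_", cl)]] * us[[paste0("uds_n_", cl)]]) / n_tests
    p <- cfg$uds_positivity[[cl]]
    expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n_tests) + 1e-12)
  }
})
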