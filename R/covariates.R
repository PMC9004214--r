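#' Closed sets used by the covariate derivations
#' @return Character vector of level codes.
#' @export
uds_drug_classes <- function() {
  c("amphetamine_type_stimulant", "fentanyl", "cocaine", "cannabis", "other_opioid")
}

#' @rdname uds_drug_classes
#' @export
region_levels <- function() {
  c("Northern_rural", "Northern_urban", "Southern_rural", "Southern_urban")
}

#' @rdname uds_drug_classes
#' @export
uds_quadrant_levels <- function() {
  c("Q0_25", "Q26_50", "Q51_75", "Q76_100")
}

#' @rdname uds_drug_classes
#' @export
age_group_levels <- function() {
  c("<25", "25-45", "46-65", "65+")
}

#' Bin a UDS positivity proportion into a quadrant
#'
#' The quarter bins `(-Inf, 0.25]`, `(0.25, 0.5]`, `(0.5, 0.75]`, `(0.75, 1]`
#' partition `[0, 1]`; a proportion of exactly 0.25 falls in the first bin and
#' 0.2501 in the second.
#'
#' @param proportion_positive numeric vector in `[0, 1]` (positive tests over
#'   total tests of one drug class).
#' @return Factor with levels `Q0_25`, `Q26_50`, `Q51_75`, `Q76_100`.
#' @export
uds_quadrant <- function(proportion_positive) {
  p <- proportion_positive
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("proportion_positive must be in [0, 1]", call. = FALSE)
  }
  cut(p, breaks = c(-Inf, 0.25, 0.5, 0.75, 1),
      labels = uds_quadrant_levels(), right = TRUE)
}

#' Average monthly urine-drug-screen frequency
#'
#' Total screening events over total days in treatment, converted to months
#' at 30.4375 days/month (365.25 / 12).
#'
#' @param n_tests nonnegative count of UDS events.
#' @param days_in_treatment positive integer; total days across episodes.
#' @return Tests per month.
#' @export
#' @examples
#' avg_monthly_uds(6, 30)  # ~6.09
avg_monthly_uds <- function(n_tests, days_in_treatment) {
  if (any(days_in_treatment < 1)) {
    stop("days_in_treatment must be at least 1", call. = FALSE)
  }
  n_tests / (days_in_treatment / 30.4375)
}

#' Classify a patient's geography into the four region strata
#'
#' Northern means health region (LHIN) code 13 or 14; rural means a Rurality
#' Index of Ontario (RIO) score of 40 or higher. Missing inputs give a missing
#' label (`NA`), which downstream analyses exclude and count.
#'
#' @param rio_score integer RIO score >= 0, or `NA`.
#' @param health_region_code integer 1-14, or `NA`.
#' @return Factor with levels `Northern_rural`, `Northern_urban`,
#'   `Southern_rural`, `Southern_urban`.
#' @export
#' @examples
#' classify_region(40, 13)  # Northern_rural
#' classify_region(39, 7)   # Southern_urban
classify_region <- function(rio_score, health_region_code) {
  code <- health_region_code
  if (any(!is.na(code) & (code < 1 | code > 14))) {
    stop("health_region_code must be in 1..14", call. = FALSE)
  }
  if (any(!is.na(rio_score) & rio_score < 0)) {
    stop("rio_score must be nonnegative", call. = FALSE)
  }
  northern <- code %in% c(13, 14)
  rural <- rio_score >= 40
  lab <- ifelse(is.na(rio_score) | is.na(code), NA_character_,
         ifelse(northern & rural, "Northern_rural",
         ifelse(northern, "Northern_urban",
         ifelse(rural, "Southern_rural", "Southern_urban"))))
  factor(lab, levels = region_levels())
}

#' Bin age at first initiation into the reporting age groups
#'
#' Fractional ages are floored to completed years; the groups partition ages
#' as `<25`, `25-45`, `46-65`, `65+` (an exactly-65-year-old falls in
#' `46-65`).
#'
#' @param age_years nonnegative numeric vector.
#' @return Factor with levels `<25`, `25-45`, `46-65`, `65+`.
#' @export
age_group <- function(age_years) {
  if (any(is.na(age_years)) || any(age_years < 0)) {
    stop("age must be nonnegative and non-missing", call. = FALSE)
  }
  a <- floor(age_years)
  lab <- ifelse(a < 25, "<25",
         ifelse(a <= 45, "25-45",
         ifelse(a <= 65, "46-65", "65+")))
  factor(lab, levels = age_group_levels())
}

#' Per-patient dose summaries with cohort above-median indicators
#'
#' The patient's starting dose is the dose of the first record of their first
#' episode; their peak dose is the maximum over all their dose records of the
#' starting medication. Medians of the peak dose are computed per medication
#' over the cohort, and both indicators compare strictly against the median
#' peak dose of the patient's starting medication (so in a one-patient cohort
#' both are `FALSE`).
#'
#' @param doses deduplicated dose-record tibble for the cohort.
#' @param episodes episode tibble from [build_episode_table()].
#' @return Tibble with one row per patient: `patient_id`,
#'   `starting_medication`, `start_dose_mg`, `peak_dose_mg`,
#'   `start_above_median`, `peak_above_median`; the per-medication medians are
#'   attached as attribute `median_peak`.
#' @export
dose_summaries <- function(doses, episodes) {
  first_ep <- episodes[episodes$episode_index == 1L,
                       c("patient_id", "starting_medication", "start_dose_mg")]
  peaks <- doses |>
    dplyr::inner_join(first_ep[, c("patient_id", "starting_medication")],
                      by = "patient_id") |>
    dplyr::filter(.data$medication == .data$starting_medication) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(peak_dose_mg = max(.data$dose_mg), .groups = "drop")
  out <- dplyr::left_join(first_ep, peaks, by = "patient_id")
  med <- c(tapply(out$peak_dose_mg, out$starting_medication, stats::median))
  out$start_above_median <- as.logical(out$start_dose_mg > med[out$starting_medication])
  out$peak_above_median <- as.logical(out$peak_dose_mg > med[out$starting_medication])
  attr(out, "median_peak") <- med
  out
}

#' Per-patient UDS summaries
#'
#' For each drug class: number of tests, positives, positivity proportion and
#' quadrant. A patient with no tests of a class gets proportion 0 (quadrant
#' `Q0_25`) and `any_tests = FALSE` so the convention is visible. The average
#' monthly UDS counts distinct (patient, date) screening events — one clinic
#' visit yields one event regardless of how many drug classes the assay
#' reports — over the patient's total days in treatment.
#'
#' @param uds UDS tibble: `patient_id`, `date`, `drug_class`, `result`
#'   (`positive`/`negative`).
#' @param histories patient-history tibble (for `patient_id`).
#' @param episodes episode tibble (for total days in treatment).
#' @return Tibble with one row per patient: `avg_monthly_uds`, and per class
#'   `uds_n_<class>`, `uds_prop_<class>`, `uds_q_<class>`, plus `any_uds`.
#' @export
uds_summaries <- function(uds, histories, episodes) {
  classes <- uds_drug_classes()
  if (nrow(uds) > 0) {
    bad <- !uds$drug_class %in% classes
    if (any(bad)) {
      stop("unknown drug_class: ", paste(unique(uds$drug_class[bad]), collapse = ", "),
           call. = FALSE)
    }
    bad_res <- !uds$result %in% c("positive", "negative")
    if (any(bad_res)) stop("result must be 'positive' or 'negative'", call. = FALSE)
  }
  days <- episodes |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(days_in_treatment = sum(.data$duration_days), .groups = "drop")

  base <- dplyr::left_join(histories["patient_id"], days, by = "patient_id")

  events <- uds |>
    dplyr::distinct(.data$patient_id, .data$date) |>
    dplyr::count(.data$patient_id, name = "n_uds_events")
  base <- dplyr::left_join(base, events, by = "patient_id") |>
    dplyr::mutate(n_uds_events = dplyr::coalesce(.data$n_uds_events, 0L),
                  avg_monthly_uds = avg_monthly_uds(.data$n_uds_events,
                                                    .data$days_in_treatment))

  per_class <- uds |>
    dplyr::count(.data$patient_id, .data$drug_class,
                 wt = as.integer(.data$result == "positive"), name = "n_pos") |>
    dplyr::left_join(dplyr::count(uds, .data$patient_id, .data$drug_class, name = "n_tests"),
                     by = c("patient_id", "drug_class"))
  wide <- tidyr::expand_grid(patient_id = base$patient_id, drug_class = classes) |>
    dplyr::left_join(per_class, by = c("patient_id", "drug_class")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n_tests, 0L),
                  n_pos = dplyr::coalesce(.data$n_pos, 0L),
                  prop = ifelse(.data$n > 0, .data$n_pos / .data$n, 0),
                  q = uds_quadrant(.data$prop)) |>
    tidyr::pivot_wider(id_cols = "patient_id", names_from = "drug_class",
                       values_from = c("n", "prop", "q"),
                       names_glue = "uds_{.value}_{drug_class}")
  out <- dplyr::left_join(base, wide, by = "patient_id")
  out$any_uds <- out$n_uds_events > 0
  out
}

#' Assemble the per-patient analysis table
#'
#' Joins the treatment histories with demographics, geography, UDS and dose
#' summaries into one row per patient — the table all downstream tabulations
#' and models consume. UDS rows for patients absent from the dose records are
#' dropped with a warning that reports the count.
#'
#' @param histories from [summarize_histories()].
#' @param uds UDS record tibble.
#' @param demographics tibble: `patient_id`, `sex` (`F`/`M`/`NA`), and either
#'   `birth_year` or `age`, plus `rio_score` and `health_region_code`.
#' @param doses deduplicated dose-record tibble.
#' @param episodes episode tibble.
#' @return A `PatientSummary` tibble: identifiers, `sex` (missing kept as the
#'   explicit category `"missing"`), `age`, `age_group`, `region`,
#'   `starting_medication`, `n_attempts`, `longest_retention_days`, `stage`,
#'   UDS columns and dose columns.
#' @export
build_patient_summaries <- function(histories, uds, demographics, doses, episodes) {
  orphan <- setdiff(unique(uds$patient_id), histories$patient_id)
  if (length(orphan) > 0) {
    warning(sprintf("%d patient(s) present in UDS but not in dose records; their %d UDS row(s) excluded",
                    length(orphan), sum(uds$patient_id %in% orphan)), call. = FALSE)
    uds <- uds[!uds$patient_id %in% orphan, , drop = FALSE]
  }

  demo <- demographics
  if (!"age" %in% names(demo)) {
    if (!"birth_year" %in% names(demo)) {
      stop("demographics needs an 'age' or 'birth_year' column", call. = FALSE)
    }
    init_year <- as.integer(format(
      histories$first_initiation_date[match(demo$patient_id, histories$patient_id)], "%Y"))
    demo$age <- init_year - demo$birth_year
  }
  demo$sex <- ifelse(is.na(demo$sex), "missing", as.character(demo$sex))
  demo$sex <- factor(demo$sex, levels = c("M", "F", "missing"))
  demo$region <- classify_region(demo$rio_score, demo$health_region_code)

  out <- histories |>
    dplyr::left_join(demo[, c("patient_id", "sex", "age", "region")], by = "patient_id") |>
    dplyr::mutate(stage = classify_stage(.data$longest_retention_days),
                  age_group = age_group(.data$age)) |>
    dplyr::left_join(dose_summaries(doses, episodes), by = "patient_id") |>
    dplyr::left_join(uds_summaries(uds, histories, episodes), by = "patient_id")
  out$starting_medication <- factor(out$starting_medication,
                                    levels = c("buprenorphine_naloxone", "methadone"))
  out
}
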