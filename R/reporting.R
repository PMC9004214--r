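#' Read UDS records from CSV
#'
#' Expects columns `patient_id`, `date` (ISO-8601), `drug_class` (one of
#' [uds_drug_classes()]), `result` (`positive`/`negative`).
#'
#' @param path CSV file path.
#' @return UDS tibble.
#' @export
read_uds_records <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("patient_id", "date", "drug_class", "result")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("UDS file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parsed <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(parsed) & !is.na(raw$date))
  if (length(bad) > 0) {
    stop(sprintf("%d UDS row(s) with unparseable dates (data line(s) %s)",
                 length(bad), paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(patient_id = raw$patient_id, date = parsed,
                 drug_class = raw$drug_class, result = raw$result)
}

#' Read patient demographics from CSV
#'
#' Expects `patient_id`, `sex`, `birth_year` (or `age`), `rio_score`,
#' `health_region_code`; empty cells become missing values.
#'
#' @param path CSV file path.
#' @return Demographics tibble.
#' @export
read_patients <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!"patient_id" %in% names(raw)) {
    stop("patients file is missing required column(s): patient_id", call. = FALSE)
  }
  out <- tibble::tibble(patient_id = raw$patient_id,
                        sex = if ("sex" %in% names(raw)) raw$sex else NA_character_)
  for (col in c("birth_year", "age", "rio_score", "health_region_code")) {
    if (col %in% names(raw)) out[[col]] <- as.numeric(raw[[col]])
  }
  out
}

#' Synthetic postal-prefix geography lookup
#'
#' Loads the small synthetic lookup table shipped with the package that maps
#' a postal-code prefix to an RIO score and health-region code. It exists to
#' exercise the geography interface in examples and tests; it is entirely
#' synthetic and carries no real geocoding information.
#'
#' @return Tibble: `postal_prefix`, `rio_score`, `health_region_code`.
#' @export
read_postal_lookup_synthetic <- function() {
  path <- system.file("extdata", "postal_rio_lookup_synthetic.csv",
                      package = "oatcascade", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    postal_prefix = readr::col_character(),
    rio_score = readr::col_integer(),
    health_region_code = readr::col_integer()))
}

#' Run the full cascade-of-care pipeline
#'
#' Orchestrates simulate/ingest, episode reconstruction, patient summaries,
#' cascade tabulations and the crude and adjusted multinomial models, writing
#' every artifact as CSV plus a JSON manifest with row counts and an
#' exclusion ledger. Exactly one of `input` (paths to the three CSVs) or
#' `simulate` (a [cohort_config()]) must be supplied; with a fixed seed the
#' run is deterministic and repeated runs write byte-identical CSVs.
#'
#' @param config a list (or path to a YAML file encoding one) with fields:
#'   `input` (list with `doses`, `uds`, `patients` paths) or `simulate` (a
#'   `cohort_config` or argument list for one); `out_dir`; optional
#'   `gap_rule` (list with `methadone_gap_days`, `buprenorphine_gap_days`),
#'   `study_end`, `alpha`, `covariates` (model covariates; defaults to the
#'   standard adjusted set).
#' @return The manifest list (files, row counts, exclusion ledger), invisibly;
#'   also written to `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    stop("config must supply exactly one of 'input' or 'simulate'", call. = FALSE)
  }
  if (is.null(config$out_dir)) stop("config needs 'out_dir'", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rule <- if (is.null(config$gap_rule)) gap_rule() else
    gap_rule(config$gap_rule$methadone_gap_days %||% 5,
             config$gap_rule$buprenorphine_gap_days %||% 6)

  if (has_sim) {
    cfg <- if (inherits(config$simulate, "cohort_config")) config$simulate else
      do.call(cohort_config, config$simulate)
    cohort <- generate_cohort(cfg)
    doses <- cohort$doses; uds <- cohort$uds; patients <- cohort$patients
    study_end <- cfg$study_end
  } else {
    doses <- read_dose_records(config$input$doses)
    uds <- read_uds_records(config$input$uds)
    patients <- read_patients(config$input$patients)
    study_end <- as.Date(config$study_end %||% max(doses$date))
  }
  alpha <- config$alpha %||% 0.05

  run_step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  episodes <- run_step("episodes", build_episode_table(doses, rule, study_end = study_end))
  histories <- run_step("histories", summarize_histories(episodes, study_end))
  summaries <- run_step("summaries",
                        build_patient_summaries(histories, uds, patients, doses, episodes))
  casc_year <- run_step("cascade_by_year", cascade_by_year(histories))
  regions <- summaries[, c("patient_id", "region")]
  casc_region <- run_step("cascade_by_region", cascade_by_region(histories, regions))

  covariates <- config$covariates %||% c(
    "sex", "age_group", "region", "starting_medication", "n_attempts",
    "avg_monthly_uds",
    paste0("uds_q_", uds_drug_classes()),
    "start_above_median", "peak_above_median")
  model_summaries <- summaries
  model_summaries$sex[model_summaries$sex == "missing"] <- NA
  model_summaries$sex <- droplevels(model_summaries$sex)
  or_crude <- run_step("crude_model",
                       fit_multinomial(model_summaries, covariates, mode = "crude", alpha = alpha))
  or_adjusted <- run_step("adjusted_model",
                          fit_multinomial(model_summaries, covariates, mode = "adjusted", alpha = alpha))
  or_table <- dplyr::bind_rows(or_crude, or_adjusted)
  table1 <- run_step("characteristics", characteristics_table(summaries, covariates))

  n_model_excluded <- attr(or_adjusted, "fits")[[1]]$n_dropped
  n_region_excluded <- attr(casc_region, "n_excluded")

  files <- list(
    episodes = "episodes.csv", patient_summaries = "patient_summaries.csv",
    cascade_by_year = "cascade_by_year.csv", cascade_by_region = "cascade_by_region.csv",
    or_table = "or_table.csv", table1 = "table1.csv")
  write_one <- function(df, file) {
    readr::write_csv(df, file.path(out_dir, file))
    nrow(df)
  }
  counts <- list(
    episodes = write_one(episodes, files$episodes),
    patient_summaries = write_one(summaries, files$patient_summaries),
    cascade_by_year = write_one(casc_year, files$cascade_by_year),
    cascade_by_region = write_one(casc_region, files$cascade_by_region),
    or_table = write_one(or_table, files$or_table),
    table1 = write_one(table1, files$table1))

  manifest <- list(
    files = files,
    row_counts = counts,
    n_patients = nrow(histories),
    exclusions = list(
      model_missing_covariates = n_model_excluded,
      regional_missing_geography = n_region_excluded),
    gap_rule = as.list(unclass(rule)),
    study_end = as.character(study_end),
    alpha = alpha)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message(sprintf(
    "pipeline complete: %d patients, %d episodes; %d excluded from models (missing covariates), %d from regional analysis (missing geography)",
    nrow(histories), nrow(episodes), n_model_excluded, n_region_excluded))
  invisible(manifest)
}
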