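#' Medication-specific disqualifying gap rule
#'
#' An episode of opioid agonist treatment ends when the patient goes a
#' medication-specific number of whole calendar days without a dose: 5 days
#' for methadone and 6 days for buprenorphine/naloxone, matching the clinical
#' guidance to re-initiate patients on starting doses after absences of these
#' durations.
#'
#' @param methadone_gap_days positive integer; dose-free days that end a
#'   methadone run (default 5).
#' @param buprenorphine_gap_days positive integer; dose-free days that end a
#'   buprenorphine/naloxone run (default 6).
#' @return A named integer vector of class `gap_rule`, keyed by medication.
#' @export
#' @examples
#' gap_rule()
#' gap_rule(methadone_gap_days = 7)
gap_rule <- function(methadone_gap_days = 5L, buprenorphine_gap_days = 6L) {
  m <- as.integer(methadone_gap_days)
  b <- as.integer(buprenorphine_gap_days)
  if (is.na(m) || m < 1L) stop("methadone_gap_days must be a positive integer", call. = FALSE)
  if (is.na(b) || b < 1L) stop("buprenorphine_gap_days must be a positive integer", call. = FALSE)
  structure(c(methadone = m, buprenorphine_naloxone = b), class = "gap_rule")
}

OAT_MEDICATIONS <- c("methadone", "buprenorphine_naloxone")

#' @keywords internal
validate_dose_records <- function(doses) {
  required <- c("patient_id", "date", "medication", "dose_mg")
  missing_cols <- setdiff(required, names(doses))
  if (length(missing_cols) > 0) {
    stop("dose records are missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!inherits(doses$date, "Date")) doses$date <- as.Date(doses$date)
  bad_med <- !doses$medication %in% OAT_MEDICATIONS
  if (any(bad_med)) {
    stop("unknown medication in dose record row(s) ",
         paste(utils::head(which(bad_med), 5), collapse = ", "),
         ": ", paste(unique(doses$medication[bad_med]), collapse = ", "),
         call. = FALSE)
  }
  if (any(doses$dose_mg < 0, na.rm = TRUE)) {
    stop("dose_mg must be nonnegative", call. = FALSE)
  }
  doses
}

#' Collapse duplicate same-day dose records
#'
#' Duplicate rows for the same (patient, date, medication) are collapsed to a
#' single record keeping the maximum dose; a warning reports how many rows
#' were dropped.
#'
#' @param doses a dose-record tibble.
#' @return Deduplicated tibble, sorted by patient, date, medication.
#' @export
dedupe_doses <- function(doses) {
  doses <- validate_dose_records(doses)
  n0 <- nrow(doses)
  # keep the maximum dose per key: sort dose descending, drop later duplicates
  # (adjacency check after the radix sort avoids hashing 3-column keys)
  ord <- order(doses$patient_id, doses$date, doses$medication, -doses$dose_mg,
               method = "radix")
  doses <- doses[ord, , drop = FALSE]
  n <- nrow(doses)
  dup <- c(FALSE,
           doses$patient_id[-1] == doses$patient_id[-n] &
             doses$date[-1] == doses$date[-n] &
             doses$medication[-1] == doses$medication[-n])
  out <- tibble::as_tibble(doses[!dup, , drop = FALSE])
  dropped <- n0 - nrow(out)
  if (dropped > 0) {
    warning(sprintf("collapsed %d duplicate (patient, date, medication) dose row(s), keeping the maximum dose", dropped),
            call. = FALSE)
  }
  out
}

#' Reconstruct treatment episodes from one patient's dose records
#'
#' Scans the patient's dosing dates in order and starts a new episode whenever
#' the run of dose-free calendar days between two consecutive dose dates
#' reaches the disqualifying gap of the medication most recently dosed
#' (equivalently, when `next_date - last_date >= gap + 1`). If both
#' medications were dosed on the last date the larger gap applies.
#'
#' @param doses dose records for a single patient (`patient_id`, `date`,
#'   `medication`, `dose_mg`); duplicates are collapsed with [dedupe_doses()].
#' @param rule a [gap_rule()].
#' @param study_end optional `Date`; doses after it are dropped with a warning
#'   (episodes are right-truncated at the study window).
#' @return A tibble of episodes: `patient_id`, `episode_index`, `start_date`,
#'   `end_date`, `duration_days` (inclusive of both endpoints, so a
#'   single-dose episode has duration 1), `starting_medication` (medication of
#'   the episode's first dose), `start_dose_mg`, `peak_dose_mg` (maximum dose
#'   of the starting medication within the episode), `n_dose_records`.
#'   Empty input returns an empty tibble.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   patient_id = "p1",
#'   date = as.Date("2015-01-01") + c(0:10, 16),
#'   medication = "methadone", dose_mg = 40
#' )
#' build_episodes(d)  # 5 dose-free days: two episodes
build_episodes <- function(doses, rule = gap_rule(), study_end = NULL) {
  if (nrow(doses) > 0 && length(unique(doses$patient_id)) > 1) {
    stop("build_episodes() takes records for one patient; see build_episode_table()",
         call. = FALSE)
  }
  build_episode_table(doses, rule = rule, study_end = study_end)
}

#' @keywords internal
#' Vectorised episode segmentation over deduplicated, sorted dose records.
episode_core <- function(doses, rule) {
  n <- nrow(doses)
  pat <- doses$patient_id
  day <- as.integer(doses$date)

  # unique (patient, date) runs; rows are sorted so duplicates are adjacent
  new_pd <- c(TRUE, pat[-1] != pat[-n] | day[-1] != day[-n])
  ud_first <- which(new_pd)
  n_ud <- length(ud_first)
  ud_id <- cumsum(new_pd)
  # gap applicable after a dose date: that date's medication (max if both)
  gap_row <- unname(rule[doses$medication])
  gap_ud <- as.vector(rowsum(gap_row, ud_id, reorder = FALSE))
  multi <- tabulate(ud_id, n_ud) > 1L
  if (any(multi)) {
    rows_multi <- ud_id %in% which(multi)
    gap_ud[multi] <- vapply(split(gap_row[rows_multi], ud_id[rows_multi]),
                            max, numeric(1))
  }

  pat_ud <- pat[ud_first]
  day_ud <- day[ud_first]
  if (n_ud == 1) {
    split_here <- logical(0)
  } else {
    same_patient <- pat_ud[-1] == pat_ud[-n_ud]
    dose_free <- day_ud[-1] - day_ud[-n_ud] - 1L
    split_here <- !same_patient | dose_free >= gap_ud[-n_ud]
  }
  ep_global <- cumsum(c(TRUE, split_here))          # per unique date
  ep_row <- rep(ep_global, times = diff(c(ud_first, n + 1L)))

  first_row <- which(!duplicated(ep_row))
  last_row <- c(first_row[-1] - 1L, n)
  start_med <- doses$medication[first_row]
  # peak over the episode's records of its starting medication
  on_start_med <- doses$medication == start_med[ep_row]
  peak <- as.vector(tapply(doses$dose_mg[on_start_med], ep_row[on_start_med], max))

  ep_pat <- pat[first_row]
  episode_index <- stats::ave(seq_along(first_row), ep_pat, FUN = seq_along)
  tibble::tibble(
    patient_id = ep_pat,
    episode_index = as.integer(episode_index),
    start_date = doses$date[first_row],
    end_date = doses$date[last_row],
    duration_days = day[last_row] - day[first_row] + 1L,
    starting_medication = start_med,
    start_dose_mg = doses$dose_mg[first_row],
    peak_dose_mg = peak,
    n_dose_records = as.integer(tabulate(ep_row))
  )
}

#' @keywords internal
empty_episode_table <- function() {
  tibble::tibble(
    patient_id = character(), episode_index = integer(),
    start_date = as.Date(character()), end_date = as.Date(character()),
    duration_days = integer(), starting_medication = character(),
    start_dose_mg = numeric(), peak_dose_mg = numeric(),
    n_dose_records = integer()
  )
}

#' Reconstruct episodes for every patient in a dose table
#'
#' @inheritParams build_episodes
#' @param doses dose records for any number of patients.
#' @return Episode tibble with one block of rows per patient (see
#'   [build_episodes()]).
#' @export
build_episode_table <- function(doses, rule = gap_rule(), study_end = NULL) {
  if (nrow(doses) == 0) return(empty_episode_table())
  doses <- dedupe_doses(doses)
  if (!is.null(study_end)) {
    study_end <- as.Date(study_end)
    late <- doses$date > study_end
    if (any(late)) {
      warning(sprintf("dropped %d dose record(s) after study_end", sum(late)), call. = FALSE)
      doses <- doses[!late, , drop = FALSE]
      if (nrow(doses) == 0) return(empty_episode_table())
    }
  }
  episode_core(doses, rule)
}

#' Summarise one patient's treatment history
#'
#' @param episodes episode tibble for one patient from [build_episodes()].
#' @param study_end `Date`; close of the study window. A patient whose last
#'   episode ends before `study_end` with no later episode is administratively
#'   lost to follow-up; an episode ending exactly at `study_end` is not.
#' @return One-row tibble: `patient_id`, `n_attempts` (number of episodes;
#'   each episode is one treatment attempt), `longest_retention_days` (the
#'   longest single episode), `first_initiation_date`, `admin_ltfu`.
#' @export
summarize_history <- function(episodes, study_end) {
  if (nrow(episodes) == 0) {
    stop("cannot summarise an empty episode list: a patient with no doses is not in the cohort",
         call. = FALSE)
  }
  study_end <- as.Date(study_end)
  tibble::tibble(
    patient_id = episodes$patient_id[1L],
    n_attempts = nrow(episodes),
    longest_retention_days = max(episodes$duration_days),
    first_initiation_date = min(episodes$start_date),
    admin_ltfu = max(episodes$end_date) < study_end
  )
}

#' Summarise treatment histories for all patients
#'
#' @param episodes episode tibble from [build_episode_table()].
#' @inheritParams summarize_history
#' @return One row per patient (see [summarize_history()]).
#' @export
summarize_histories <- function(episodes, study_end) {
  if (nrow(episodes) == 0) {
    stop("cannot summarise an empty episode table", call. = FALSE)
  }
  study_end <- as.Date(study_end)
  episodes |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_attempts = dplyr::n(),
      longest_retention_days = max(.data$duration_days),
      first_initiation_date = min(.data$start_date),
      admin_ltfu = max(.data$end_date) < study_end,
      .groups = "drop")
}

#' Read dose records from CSV
#'
#' Expects columns `patient_id`, `date` (ISO-8601), `medication`
#' (`methadone` or `buprenorphine_naloxone`), `dose_mg`. Duplicate
#' (patient, date, medication) rows are collapsed with a warning; rows with
#' unparseable dates raise an error naming their line numbers.
#'
#' @param path CSV file path.
#' @return Deduplicated dose-record tibble.
#' @export
read_dose_records <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("patient_id", "date", "medication", "dose_mg")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("dose-record file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parsed <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(parsed) & !is.na(raw$date))
  if (length(bad) > 0) {
    stop(sprintf("%d dose row(s) with unparseable dates (data line(s) %s)",
                 length(bad), paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  doses <- tibble::tibble(
    patient_id = raw$patient_id,
    date = parsed,
    medication = raw$medication,
    dose_mg = as.numeric(raw$dose_mg)
  )
  dedupe_doses(doses)
}

#' Write an episode table to CSV
#'
#' @param path output CSV path.
#' @param episodes episode tibble.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(path, episodes) {
  readr::write_csv(episodes, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
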