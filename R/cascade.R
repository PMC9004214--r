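#' Cascade-of-care stage levels
#'
#' Internal codes and display labels for the four retention stages.
#' @return Named character vector mapping codes to display labels.
#' @export
cascade_stages <- function() {
  c(LT_90 = "Less than 90 days",
    D90_365 = "90 to 365 days",
    Y1_2 = "One to two years",
    GT_2Y = "Over two years")
}

#' Classify longest retention into a cascade stage
#'
#' Stages partition the nonnegative durations as `[0, 90)`, `[90, 365]`,
#' `(365, 730]`, `(730, Inf)`; one year is taken as 365 days and two years as
#' 730 (leap days ignored).
#'
#' @param longest_retention_days nonnegative integer vector of days retained.
#' @return Factor with levels `LT_90`, `D90_365`, `Y1_2`, `GT_2Y`.
#' @export
#' @examples
#' classify_stage(c(89, 90, 365, 366, 730, 731))
classify_stage <- function(longest_retention_days) {
  d <- longest_retention_days
  if (any(is.na(d))) stop("retention duration must not be missing", call. = FALSE)
  if (any(d < 0)) stop("retention duration must be nonnegative", call. = FALSE)
  codes <- names(cascade_stages())
  idx <- findInterval(d, c(90, 365 + 1e-9, 730 + 1e-9)) + 1L
  factor(codes[idx], levels = codes)
}

#' @keywords internal
cascade_counts <- function(stage, stratum) {
  tab <- table(factor(stage, levels = names(cascade_stages())))
  tibble::tibble(
    stratum = stratum,
    stage = factor(names(tab), levels = names(cascade_stages())),
    count = as.integer(tab),
    total = sum(tab),
    proportion = as.integer(tab) / sum(tab)
  )
}

#' Tabulate the cascade of care by year of first initiation
#'
#' @param histories patient-history tibble from [summarize_histories()] (needs
#'   `longest_retention_days` and `first_initiation_date`).
#' @return Tidy cascade table: one row per (initiation year, stage) with
#'   `count`, `total` and `proportion` (proportions within a year sum to 1).
#' @export
cascade_by_year <- function(histories) {
  if (nrow(histories) == 0) stop("histories must be non-empty", call. = FALSE)
  stage <- classify_stage(histories$longest_retention_days)
  year <- format(histories$first_initiation_date, "%Y")
  purrr::map(sort(unique(year)),
             ~ cascade_counts(stage[year == .x], .x)) |>
    purrr::list_rbind()
}

#' Tabulate the cascade of care by geographic region
#'
#' Patients with missing region are excluded from the tables and counted in
#' the `n_excluded` attribute, mirroring a cohort in which patients without a
#' postal code cannot be placed in a health region.
#'
#' @param histories patient-history tibble (needs `patient_id`,
#'   `longest_retention_days`).
#' @param regions tibble with `patient_id` and `region` (one of
#'   `Northern_rural`, `Northern_urban`, `Southern_rural`, `Southern_urban`,
#'   or `NA` for missing).
#' @return Tidy cascade table keyed by region, with attribute `n_excluded`.
#' @export
cascade_by_region <- function(histories, regions) {
  joined <- dplyr::left_join(histories, regions[, c("patient_id", "region")],
                             by = "patient_id")
  known <- region_levels()
  bad <- !is.na(joined$region) & !joined$region %in% known
  if (any(bad)) {
    stop("unknown region label(s): ",
         paste(unique(joined$region[bad]), collapse = ", "), call. = FALSE)
  }
  n_excluded <- sum(is.na(joined$region))
  joined <- joined[!is.na(joined$region), , drop = FALSE]
  stage <- classify_stage(joined$longest_retention_days)
  out <- purrr::map(known[known %in% joined$region],
                    ~ cascade_counts(stage[joined$region == .x], .x)) |>
    purrr::list_rbind()
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Round half-up to a fixed number of decimals
#'
#' Display rounding used throughout the reports (base `round()` rounds half to
#' even, which does not match the convention of the printed tables).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a proportion as a display percentage
#'
#' @param p proportion in `[0, 1]`.
#' @param digits decimals of the percentage (0 for the yearly cascade, 1 for
#'   characteristics tables, 2 where finer precision is reported).
#' @return Numeric percentage rounded half-up.
#' @export
#' @examples
#' percent_of(873, 1867)        # 47
#' percent_of(7247, 32487, 2)   # 22.31
percent_of <- function(count, total, digits = 0) {
  round_half_up(100 * count / total, digits)
}
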