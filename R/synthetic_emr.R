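#' Configuration for the synthetic EMR cohort generator
#'
#' Defines the study conditions the generator emulates: a multi-clinic OAT
#' cohort observed 2014-2020 with daily (or near-daily) dosing runs separated
#' by planted dose-free gaps, per-drug-class UDS positivity, and a cohort mix
#' over four geographic strata. Defaults follow the cohort composition the
#' pipeline is designed for: 77.6% methadone starts, sex mix 61.4% M / 38.5%
#' F with a sliver missing, age Normal(35.6, 10.7) truncated at 18, region
#' mix (Northern rural 4.3%, Northern urban 17.9%, Southern rural 3.4%,
#' Southern urban 74.4%), and about 6 UDS events per treatment month.
#'
#' Distributions are given as `list(name=, ...)` with `name` one of
#' `"fixed"` (`value`), `"geometric"` (`mean` extra days above `min`),
#' `"lognormal"` (`meanlog`, `sdlog`), or `"poisson"` (`lambda`); all draws
#' are clamped to at least `min` (default 1 day).
#'
#' @param n_patients positive patient count.
#' @param study_start,study_end study window dates.
#' @param medication_mix probability a patient starts on methadone.
#' @param episode_length_distribution distribution of episode lengths (days).
#' @param inter_episode_gap_distribution distribution of dose-free days
#'   between consecutive episodes; draws are clamped up to the medication's
#'   disqualifying gap so planted attempt counts stay recoverable.
#' @param attempts_distribution distribution of the target number of
#'   treatment attempts per patient (episodes stop early at `study_end`).
#' @param dosing_miss_probability per-day probability of a skipped dose
#'   inside an episode, in `[0, 1)`; consecutive missed-day runs are capped
#'   strictly below the disqualifying gap so planted episodes cannot
#'   self-split.
#' @param uds_rate_per_month nonnegative UDS event rate per treatment month.
#' @param uds_positivity named probabilities per drug class in `[0, 1]`.
#' @param region_mix probabilities over the four region strata; must sum to 1.
#' @param sex_mix probabilities over `M`, `F`, `missing`; must sum to 1.
#' @param age_mean,age_sd,age_min age distribution (Normal, truncated below).
#' @param dose_ramp per-medication `c(start, peak)` dose in mg; doses ramp
#'   linearly from start to peak over `ramp_days` days then hold.
#' @param ramp_days days of the dose ramp.
#' @param gap_rule the [gap_rule()] the cohort is generated to respect.
#' @param seed integer seed; all randomness in [generate_cohort()] flows from
#'   it with no global RNG side effects.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 500,
                          study_start = as.Date("2014-01-01"),
                          study_end = as.Date("2020-12-31"),
                          medication_mix = 0.776,
                          episode_length_distribution = list(name = "lognormal", meanlog = log(365), sdlog = 1.5),
                          inter_episode_gap_distribution = list(name = "geometric", mean = 60),
                          attempts_distribution = list(name = "poisson", lambda = 1.17),
                          dosing_miss_probability = 0.15,
                          uds_rate_per_month = 6.05,
                          uds_positivity = c(amphetamine_type_stimulant = 0.12,
                                             fentanyl = 0.15, cocaine = 0.25,
                                             cannabis = 0.35, other_opioid = 0.18),
                          region_mix = c(Northern_rural = 0.043, Northern_urban = 0.179,
                                         Southern_rural = 0.034, Southern_urban = 0.744),
                          sex_mix = c(M = 0.614, F = 0.385, missing = 0.001),
                          age_mean = 35.6, age_sd = 10.7, age_min = 18,
                          dose_ramp = list(methadone = c(start = 30, peak = 80),
                                           buprenorphine_naloxone = c(start = 8, peak = 16)),
                          ramp_days = 30,
                          gap_rule = oatcascade::gap_rule(),
                          seed = 1L) {
  cfg <- list(n_patients = n_patients, study_start = as.Date(study_start),
              study_end = as.Date(study_end), medication_mix = medication_mix,
              episode_length_distribution = episode_length_distribution,
              inter_episode_gap_distribution = inter_episode_gap_distribution,
              attempts_distribution = attempts_distribution,
              dosing_miss_probability = dosing_miss_probability,
              uds_rate_per_month = uds_rate_per_month,
              uds_positivity = uds_positivity, region_mix = region_mix,
              sex_mix = sex_mix, age_mean = age_mean, age_sd = age_sd,
              age_min = age_min, dose_ramp = dose_ramp, ramp_days = ramp_days,
              gap_rule = gap_rule, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' @keywords internal
validate_cohort_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
      stop("configuration error: ", field, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 0) {
    stop("configuration error: n_patients must be a nonnegative count", call. = FALSE)
  }
  if (cfg$study_end < cfg$study_start) {
    stop("configuration error: study_end is before study_start", call. = FALSE)
  }
  chk_prob(cfg$medication_mix, "medication_mix")
  chk_prob(cfg$dosing_miss_probability, "dosing_miss_probability")
  if (cfg$dosing_miss_probability >= 1) {
    stop("configuration error: dosing_miss_probability must be < 1", call. = FALSE)
  }
  if (cfg$uds_rate_per_month < 0) {
    stop("configuration error: uds_rate_per_month must be nonnegative", call. = FALSE)
  }
  chk_prob(cfg$uds_positivity, "uds_positivity")
  if (!setequal(names(cfg$uds_positivity), uds_drug_classes())) {
    stop("configuration error: uds_positivity must name every drug class", call. = FALSE)
  }
  chk_prob(cfg$region_mix, "region_mix")
  if (abs(sum(cfg$region_mix) - 1) > 1e-9) {
    stop("configuration error: region_mix must sum to 1", call. = FALSE)
  }
  if (!setequal(names(cfg$region_mix), region_levels())) {
    stop("configuration error: region_mix must name the four region strata", call. = FALSE)
  }
  chk_prob(cfg$sex_mix, "sex_mix")
  if (abs(sum(cfg$sex_mix) - 1) > 1e-9) {
    stop("configuration error: sex_mix must sum to 1", call. = FALSE)
  }
  cfg
}

#' @keywords internal
draw_days <- function(dist, n, min = 1L) {
  x <- switch(dist$name,
    fixed = rep(dist$value, n),
    geometric = stats::rgeom(n, prob = 1 / (dist$mean + 1)),
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
    poisson = stats::rpois(n, dist$lambda),
    stop("configuration error: unknown distribution '", dist$name, "'", call. = FALSE)
  )
  pmax(as.integer(round(x)), as.integer(min))
}

#' @keywords internal
#' Dosing days within one episode: daily with per-day misses; first and last
#' day always dosed and consecutive miss runs forced strictly below `gap`.
dosing_days <- function(duration, miss_prob, gap) {
  if (duration <= 2 || miss_prob == 0) {
    dosed <- rep(TRUE, duration)
    if (duration > 2 && miss_prob > 0) dosed[2:(duration - 1)] <- stats::runif(duration - 2) >= miss_prob
    return(which(dosed))
  }
  dosed <- rep(TRUE, duration)
  dosed[2:(duration - 1)] <- stats::runif(duration - 2) >= miss_prob
  # cap miss runs at gap - 1 by forcing a dose on every gap-th missed day
  r <- rle(dosed)
  ends <- cumsum(r$lengths)
  for (j in which(!r$values & r$lengths >= gap)) {
    run_start <- ends[j] - r$lengths[j] + 1L
    force_at <- run_start + seq(gap - 1L, r$lengths[j] - 1L, by = gap)
    dosed[force_at] <- TRUE
  }
  which(dosed)
}

#' Generate a seeded synthetic EMR cohort with ground truth
#'
#' Emits the three tables the pipeline consumes — dose records, UDS records
#' and demographics — together with the planted ground truth (episodes, stage,
#' region, empirical UDS positivity) so episode reconstruction, staging and
#' tabulation can be tested for exact recovery. Identical `config` (including
#' its seed) gives identical output; the global RNG state is untouched.
#'
#' @param config a [cohort_config()].
#' @return List of tibbles: `doses`, `uds`, `patients`, and `truth` (a list
#'   with `episodes`, `patients` including planted stage/region, and the
#'   configured positivity).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

#' @keywords internal
generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  if (n == 0) {
    return(list(doses = empty_dose_table(), uds = empty_uds_table(),
                patients = empty_patient_table(),
                truth = list(episodes = empty_truth_episodes(),
                             patients = empty_truth_patients(),
                             uds_positivity = cfg$uds_positivity)))
  }
  ids <- sprintf("P%05d", seq_len(n))
  window_days <- as.integer(cfg$study_end - cfg$study_start) + 1L

  medication <- ifelse(stats::runif(n) < cfg$medication_mix,
                       "methadone", "buprenorphine_naloxone")
  sex <- sample(names(cfg$sex_mix), n, replace = TRUE, prob = cfg$sex_mix)
  age <- pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd), cfg$age_min)
  region <- sample(names(cfg$region_mix), n, replace = TRUE, prob = cfg$region_mix)
  northern <- grepl("^Northern", region)
  rural <- grepl("rural$", region)
  health_region_code <- ifelse(northern, sample(13:14, n, replace = TRUE),
                               sample(1:12, n, replace = TRUE))
  rio_score <- ifelse(rural, sample(40:100, n, replace = TRUE),
                      sample(0:39, n, replace = TRUE))
  n_attempts_target <- 1L + draw_days(cfg$attempts_distribution, n, min = 0L)

  dose_rows <- vector("list", n)
  uds_rows <- vector("list", n)
  truth_eps <- vector("list", n)
  for (i in seq_len(n)) {
    med <- medication[i]
    med_gap <- unname(cfg$gap_rule[med])
    ramp <- cfg$dose_ramp[[med]]
    start <- cfg$study_start + sample.int(window_days, 1L) - 1L
    eps <- list()
    for (e in seq_len(n_attempts_target[i])) {
      if (start > cfg$study_end) break
      len <- draw_days(cfg$episode_length_distribution, 1L)
      end <- min(start + len - 1L, cfg$study_end)
      eps[[e]] <- c(as.integer(start), as.integer(end))
      gap_days <- max(draw_days(cfg$inter_episode_gap_distribution, 1L), med_gap)
      start <- end + gap_days + 1L
    }
    ep_mat <- do.call(rbind, eps)
    truth_eps[[i]] <- tibble::tibble(
      patient_id = ids[i], episode_index = seq_len(nrow(ep_mat)),
      start_date = as.Date(ep_mat[, 1], origin = "1970-01-01"),
      end_date = as.Date(ep_mat[, 2], origin = "1970-01-01"),
      medication = med)

    ep_dose_dates <- lapply(seq_len(nrow(ep_mat)), function(e) {
      dur <- ep_mat[e, 2] - ep_mat[e, 1] + 1L
      days <- dosing_days(dur, cfg$dosing_miss_probability, med_gap)
      ep_mat[e, 1] + days - 1L
    })
    all_days <- unlist(ep_dose_dates)
    day_in_ep <- unlist(lapply(ep_dose_dates, function(d) d - d[1] + 1L))
    dose <- ramp["start"] + (ramp["peak"] - ramp["start"]) *
      pmin((day_in_ep - 1) / cfg$ramp_days, 1)
    dose_rows[[i]] <- tibble::tibble(
      patient_id = ids[i],
      date = as.Date(all_days, origin = "1970-01-01"),
      medication = med, dose_mg = round(unname(dose), 1))

    # UDS events at the configured monthly rate over each episode
    n_events <- stats::rpois(nrow(ep_mat),
                             cfg$uds_rate_per_month * (ep_mat[, 2] - ep_mat[, 1] + 1L) / 30.4375)
    if (sum(n_events) > 0) {
      ev_dates <- unlist(lapply(seq_len(nrow(ep_mat)), function(e) {
        if (n_events[e] == 0) return(integer(0))
        ep_mat[e, 1] + sample.int(ep_mat[e, 2] - ep_mat[e, 1] + 1L, n_events[e],
                                  replace = TRUE) - 1L
      }))
      ev_dates <- sort(unique(ev_dates))
      classes <- uds_drug_classes()
      uds_rows[[i]] <- tibble::tibble(
        patient_id = ids[i],
        date = rep(as.Date(ev_dates, origin = "1970-01-01"), each = length(classes)),
        drug_class = rep(classes, times = length(ev_dates)),
        result = ifelse(stats::runif(length(ev_dates) * length(classes)) <
                          cfg$uds_positivity[rep(classes, times = length(ev_dates))],
                        "positive", "negative"))
    }
  }

  doses <- purrr::list_rbind(dose_rows)
  uds <- purrr::list_rbind(uds_rows[!vapply(uds_rows, is.null, logical(1))])
  if (nrow(uds) == 0) uds <- empty_uds_table()
  truth_episodes <- purrr::list_rbind(truth_eps)

  first_init <- truth_episodes |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_initiation_date = min(.data$start_date),
                     longest = max(as.integer(.data$end_date - .data$start_date) + 1L),
                     n_episodes = dplyr::n(), .groups = "drop")
  birth_year <- as.integer(format(first_init$first_initiation_date, "%Y")) -
    as.integer(floor(age))

  pos_emp <- if (nrow(uds) > 0) {
    uds |>
      dplyr::group_by(.data$patient_id, .data$drug_class) |>
      dplyr::summarise(prop_positive = mean(.data$result == "positive"), .groups = "drop")
  } else {
    tibble::tibble(patient_id = character(), drug_class = character(),
                   prop_positive = numeric())
  }

  patients <- tibble::tibble(
    patient_id = ids,
    sex = ifelse(sex == "missing", NA_character_, sex),
    birth_year = birth_year,
    rio_score = as.integer(rio_score),
    health_region_code = as.integer(health_region_code))

  truth_patients <- tibble::tibble(
    patient_id = ids,
    starting_medication = medication,
    region = region,
    n_episodes = first_init$n_episodes,
    longest_retention_days = first_init$longest,
    stage = classify_stage(first_init$longest))

  list(doses = doses, uds = uds, patients = patients,
       truth = list(episodes = truth_episodes, patients = truth_patients,
                    uds_positivity = cfg$uds_positivity,
                    uds_empirical_positivity = pos_emp))
}

#' @keywords internal
empty_dose_table <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 medication = character(), dose_mg = numeric())
}
#' @keywords internal
empty_uds_table <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 drug_class = character(), result = character())
}
#' @keywords internal
empty_patient_table <- function() {
  tibble::tibble(patient_id = character(), sex = character(),
                 birth_year = integer(), rio_score = integer(),
                 health_region_code = integer())
}
#' @keywords internal
empty_truth_episodes <- function() {
  tibble::tibble(patient_id = character(), episode_index = integer(),
                 start_date = as.Date(character()), end_date = as.Date(character()),
                 medication = character())
}
#' @keywords internal
empty_truth_patients <- function() {
  tibble::tibble(patient_id = character(), starting_medication = character(),
                 region = character(), n_episodes = integer(),
                 longest_retention_days = integer(),
                 stage = factor(character(), levels = names(cascade_stages())))
}

#' Generate a patient-summary cohort from known stage-membership odds
#'
#' Simulation harness for odds-ratio recovery: draws covariates (independent
#' Bernoulli(0.5) for every non-intercept coefficient name) and samples the
#' cascade stage from the baseline-category logit implied by the supplied
#' coefficients, returning the generating coefficients alongside so a fitted
#' model can be checked against truth.
#'
#' @param stage_log_odds numeric matrix of log-odds coefficients: one column
#'   per non-reference stage (`D90_365`, `Y1_2`, `GT_2Y`), rows named by
#'   coefficient (an `"(Intercept)"` row is optional and defaults to 0).
#' @param n number of patients (0 gives an empty table).
#' @param seed integer seed.
#' @return List: `summaries` (tibble with `patient_id`, `stage` and one 0/1
#'   column per covariate) and `coefficients` (the generating matrix,
#'   intercept row included).
#' @export
#' @examples
#' b <- matrix(0, 1, 3, dimnames = list("x", c("D90_365", "Y1_2", "GT_2Y")))
#' b["x", "GT_2Y"] <- log(2)
#' cohort <- generate_stage_odds_cohort(b, n = 1000, seed = 1)
generate_stage_odds_cohort <- function(stage_log_odds, n, seed = 1L) {
  if (!all(is.finite(stage_log_odds))) {
    stop("stage_log_odds must be finite", call. = FALSE)
  }
  stages <- names(cascade_stages())
  if (is.null(colnames(stage_log_odds))) colnames(stage_log_odds) <- stages[-1]
  if (!identical(colnames(stage_log_odds), stages[-1])) {
    stop("stage_log_odds columns must be ", paste(stages[-1], collapse = ", "),
         call. = FALSE)
  }
  B <- stage_log_odds
  if (!"(Intercept)" %in% rownames(B)) {
    B <- rbind(`(Intercept)` = c(0, 0, 0), B)
  }
  covs <- setdiff(rownames(B), "(Intercept)")
  if (n == 0) {
    out <- tibble::tibble(patient_id = character(),
                          stage = factor(character(), levels = stages))
    for (cv in covs) out[[cv]] <- numeric(0)
    return(list(summaries = out, coefficients = B))
  }
  withr::with_seed(as.integer(seed), {
    X <- cbind(`(Intercept)` = 1,
               matrix(stats::rbinom(n * length(covs), 1, 0.5), n, length(covs),
                      dimnames = list(NULL, covs)))
    eta <- X %*% B[colnames(X), , drop = FALSE]
    P <- cbind(1, exp(eta))
    P <- P / rowSums(P)
    u <- stats::runif(n)
    idx <- rowSums(u > t(apply(P, 1, cumsum))) + 1L
    out <- tibble::tibble(patient_id = sprintf("S%06d", seq_len(n)),
                          stage = factor(stages[idx], levels = stages))
    for (cv in covs) out[[cv]] <- X[, cv]
    list(summaries = out, coefficients = B)
  })
}
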