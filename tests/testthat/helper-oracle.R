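# Brute-force day-scan episode oracle, written independently of the package's
# vectorised builder: walk every calendar day, count consecutive dose-free
# days, and close the episode when the run reaches the disqualifying gap of
# the medication(s) dosed on the most recent dosing day (max if both).
oracle_episodes <- function(dates, meds, rule = gap_rule()) {
  keep <- !duplicated(data.frame(dates, meds))
  dates <- dates[keep]; meds <- meds[keep]
  o <- order(dates, meds)
  dates <- dates[o]; meds <- meds[o]
  days <- seq(min(dates), max(dates), by = "day")
  dosed <- days %in% dates
  starts <- ends <- as.Date(character())
  cur_start <- days[1]
  last_dosed <- days[1]
  run <- 0L
  gap_needed <- max(unname(rule[meds[dates == days[1]]]))
  for (i in seq_along(days)[-1]) {
    if (dosed[i]) {
      if (run >= gap_needed) {
        starts <- c(starts, cur_start)
        ends <- c(ends, last_dosed)
        cur_start <- days[i]
      }
      last_dosed <- days[i]
      gap_needed <- max(unname(rule[meds[dates == days[i]]]))
      run <- 0L
    } else {
      run <- run + 1L
    }
  }
  starts <- c(starts, cur_start)
  ends <- c(ends, last_dosed)
  tibble::tibble(start_date = starts, end_date = ends,
                 duration_days = as.integer(ends - starts) + 1L)
}

# Random small dose history: <= 30 doses within a 60-day span, both
# medications allowed.
random_dose_history <- function(id = "px", max_span = 60, max_doses = 30,
                                mixed = TRUE) {
  n <- sample.int(max_doses, 1)
  offs <- sort(sample.int(max_span, n, replace = TRUE)) - 1L
  meds <- if (mixed) {
    sample(c("methadone", "buprenorphine_naloxone"), n, replace = TRUE)
  } else {
    rep(sample(c("methadone", "buprenorphine_naloxone"), 1), n)
  }
  tibble::tibble(patient_id = id,
                 date = as.Date("2016-03-01") + offs,
                 medication = meds,
                 dose_mg = sample(c(8, 16, 30, 60, 90), n, replace = TRUE))
}

expect_oracle_agreement <- function(doses, rule = gap_rule()) {
  built <- suppressWarnings(build_episodes(doses, rule))
  orc <- oracle_episodes(doses$date, doses$medication, rule)
  expect_equal(nrow(built), nrow(orc))
  expect_equal(built$start_date, orc$start_date)
  expect_equal(built$end_date, orc$end_date)
  expect_equal(built$duration_days, orc$duration_days)
}
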