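mk_doses <- function(offsets, med = "methadone", dose = 40, id = "p1",
                     origin = as.Date("2015-01-01")) {
  tibble::tibble(patient_id = id, date = origin + offsets,
                 medication = med, dose_mg = dose)
}

test_that("gap rule splits methadone runs at 5 dose-free days, not 4", {
  # days 0..10 plus day 15: only 4 dose-free days -> one episode
  eps <- build_episodes(mk_doses(c(0:10, 15)))
  expect_equal(nrow(eps), 1)
  expect_equal(eps$duration_days, 16L)

  # days 0..10 plus day 16: 5 dose-free days ends the episode
  eps2 <- build_episodes(mk_doses(c(0:10, 16)))
  expect_equal(nrow(eps2), 2)
  expect_equal(eps2$duration_days, c(11L, 1L))
  expect_equal(eps2$start_date, as.Date("2015-01-01") + c(0, 16))
})

test_that("buprenorphine uses a 6-day gap", {
  expect_equal(nrow(build_episodes(mk_doses(c(0, 6), med = "buprenorphine_naloxone"))), 1)
  expect_equal(nrow(build_episodes(mk_doses(c(0, 7), med = "buprenorphine_naloxone"))), 2)
})

test_that("single dose gives one episode of duration 1", {
  eps <- build_episodes(mk_doses(0))
  expect_equal(nrow(eps), 1)
  expect_equal(eps$duration_days, 1L)
  expect_equal(eps$start_date, eps$end_date)
})

test_that("the applicable gap follows the most recently dosed medication", {
  # last dose before the break is buprenorphine -> 5 dose-free days tolerated
  d <- dplyr::bind_rows(mk_doses(0:3),
                        mk_doses(4, med = "buprenorphine_naloxone"),
                        mk_doses(10))
  expect_equal(nrow(build_episodes(d)), 1)
  # last dose methadone -> the same 5-day break splits
  d2 <- dplyr::bind_rows(mk_doses(c(0:4, 10)))
  expect_equal(nrow(build_episodes(d2)), 2)
})

test_that("episode metadata: starting medication, start and peak dose", {
  d <- dplyr::bind_rows(
    mk_doses(0, dose = 30),
    mk_doses(1:5, dose = c(40, 50, 60, 55, 45)),
    mk_doses(2:4, med = "buprenorphine_naloxone", dose = 99))
  eps <- build_episodes(d)
  expect_equal(eps$starting_medication, "methadone")
  expect_equal(eps$start_dose_mg, 30)
  expect_equal(eps$peak_dose_mg, 60)  # bup doses don't set the peak
})

test_that("duplicate (patient, date, medication) rows collapse to the max dose", {
  d <- dplyr::bind_rows(mk_doses(0:2, dose = 40), mk_doses(1, dose = 70))
  expect_warning(out <- dedupe_doses(d), "1 duplicate")
  expect_equal(nrow(out), 3)
  expect_equal(out$dose_mg[out$date == as.Date("2015-01-02")], 70)
})

test_that("row order does not affect the reconstruction", {
  withr::with_seed(11, {
    d <- random_dose_history()
    shuffled <- d[sample.int(nrow(d)), ]
    expect_equal(suppressWarnings(build_episodes(d)),
                 suppressWarnings(build_episodes(shuffled)))
  })
})

test_that("records are conserved across episodes and empty input is not an error", {
  withr::with_seed(12, {
    for (i in 1:20) {
      d <- random_dose_history()
      d_unique <- suppressWarnings(dedupe_doses(d))
      eps <- suppressWarnings(build_episodes(d))
      expect_equal(sum(eps$n_dose_records), nrow(d_unique))
    }
  })
  expect_equal(nrow(build_episodes(mk_doses(integer(0)))), 0)
})

test_that("appending a dose inside the grace window never adds an episode; beyond it always does", {
  withr::with_seed(13, {
    for (i in 1:25) {
      d <- random_dose_history(mixed = FALSE)
      eps <- suppressWarnings(build_episodes(d))
      gap <- unname(gap_rule()[d$medication[1]])
      last_end <- max(eps$end_date)
      inside <- dplyr::bind_rows(d, mk_doses(0, med = d$medication[1], id = d$patient_id[1],
                                             origin = last_end + gap - 1))
      beyond <- dplyr::bind_rows(d, mk_doses(0, med = d$medication[1], id = d$patient_id[1],
                                             origin = last_end + gap + 1))
      expect_equal(nrow(suppressWarnings(build_episodes(inside))), nrow(eps))
      expect_equal(nrow(suppressWarnings(build_episodes(beyond))), nrow(eps) + 1L)
    }
  })
})

test_that("builder agrees with the brute-force day-scan oracle on random histories", {
  withr::with_seed(14, {
    for (i in 1:300) {
      expect_oracle_agreement(random_dose_history())
    }
  })
})

test_that("unknown medications and missing columns are rejected by name", {
  bad <- mk_doses(0:2); bad$medication <- "suboxone"
  expect_error(build_episodes(bad), "unknown medication")
  expect_error(build_episode_table(tibble::tibble(patient_id = "p", med = "methadone")),
               "missing required column")
})

test_that("doses after study_end are dropped with a warning and episodes truncate", {
  d <- mk_doses(0:20)
  expect_warning(eps <- build_episodes(d, study_end = as.Date("2015-01-11")),
                 "after study_end")
  expect_equal(eps$end_date, as.Date("2015-01-11"))
})

test_that("history summary counts attempts, longest retention and admin LTFU", {
  eps <- build_episodes(mk_doses(c(0:10, 16)))
  h <- summarize_history(eps, study_end = as.Date("2015-12-31"))
  expect_equal(h$n_attempts, 2L)
  expect_equal(h$longest_retention_days, 11L)
  expect_equal(h$first_initiation_date, as.Date("2015-01-01"))
  expect_true(h$admin_ltfu)

  # episode ending exactly at study_end is not lost to follow-up
  h2 <- summarize_history(build_episodes(mk_doses(0:9)),
                          study_end = as.Date("2015-01-10"))
  expect_false(h2$admin_ltfu)
  expect_error(summarize_history(build_episodes(mk_doses(integer(0))), Sys.Date()),
               "empty episode")
})

test_that("dose records survive a CSV round trip and schema errors name columns", {
  d <- mk_doses(0:2)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d, path)
  expect_equal(read_dose_records(path), d)

  bad <- d; names(bad)[3] <- "med"
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path2)
  expect_error(read_dose_records(path2), "medication")

  ugly <- d; ugly$date <- c("2015-01-01", "not-a-date", "2015-01-03")
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ugly, path3)
  expect_error(read_dose_records(path3), "unparseable date")

  ep_path <- withr::local_tempfile(fileext = ".csv")
  write_episodes(ep_path, build_episodes(d))
  expect_true(file.exists(ep_path))
})
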