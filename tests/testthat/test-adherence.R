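simple_regimen <- function(am = 1L, pm = 1L, days = 5L) {
  tibble::tibble(participant_id = "P1",
                 enrollment_date = as.Date("2015-08-01"),
                 end_date = as.Date("2015-08-01") + days - 1L,
                 am_doses = am, pm_doses = pm)
}

ctrl_events <- function(times, pid = "P1") {
  tibble::tibble(participant_id = pid,
                 timestamp = as.POSIXct(times, tz = "UTC"),
                 medication = "controller", source = "device")
}

test_that("window boundaries are half-open: 11:59 is AM, 12:00 exactly is PM", {
  ev <- ctrl_events(c("2015-08-01 11:59:00", "2015-08-01 12:00:00",
                      "2015-08-02 07:00:00", "2015-08-02 07:01:00",
                      "2015-08-02 19:00:00"))
  w <- assign_windows(ev, simple_regimen())
  d1 <- w[w$date == as.Date("2015-08-01"), ]
  expect_equal(c(d1$am_count, d1$pm_count), c(1L, 1L))
  d2 <- w[w$date == as.Date("2015-08-02"), ]
  expect_equal(c(d2$am_count, d2$pm_count), c(2L, 1L))
})

test_that("events outside the enrollment window are excluded and logged", {
  ev <- ctrl_events(c("2015-07-31 08:00:00", "2015-08-02 08:00:00",
                      "2015-09-15 08:00:00"))
  w <- assign_windows(ev, simple_regimen())
  expect_equal(sum(w$am_count) + sum(w$pm_count), 1L)
  expect_equal(nrow(attr(w, "discard_log")), 2L)
})

test_that("window adherence caps at 1 and is undefined without a prescription", {
  expect_equal(window_adherence(1, 1), 1)
  expect_equal(window_adherence(3, 1), 1)   # capped
  expect_equal(window_adherence(1, 2), 0.5)
  expect_true(is.na(window_adherence(2, 0)))
  expect_error(window_adherence(-1, 1), "non-negative")
})

test_that("daily adherence averages the defined windows", {
  expect_equal(daily_adherence(1, 0, 1, 1), 0.5)
  expect_equal(daily_adherence(1, 0, 1, 0), 1)    # once-daily regimen
  expect_equal(daily_adherence(5, 0, 2, 2), 0.5)  # AM capped, PM missed
  expect_true(is.na(daily_adherence(0, 0, 0, 0)))
})

test_that("group adherence is the unweighted mean over defined days", {
  d <- make_daily(participant_id = "P1", study_day = 0:3,
                  daily_adherence = c(1, 0, 0.5, 0.5))
  expect_equal(group_adherence(d), 0.5)
  expect_equal(group_adherence(make_daily(participant_id = "P1", study_day = 0,
                                          daily_adherence = 0.3)), 0.3)
  expect_error(group_adherence(make_daily(participant_id = "P1", study_day = 0,
                                          daily_adherence = NA_real_)),
               class = "adhema_empty_error")
})

test_that("group adherence of a pooled cohort lies between the parts", {
  withr::local_seed(11)
  for (rep in 1:20) {
    a <- make_daily(participant_id = "A", study_day = 0:9,
                    daily_adherence = round(runif(10), 2))
    b <- make_daily(participant_id = "B", study_day = 0:4,
                    daily_adherence = round(runif(5), 2))
    pooled <- group_adherence(dplyr::bind_rows(a, b))
    expect_gte(pooled, min(group_adherence(a), group_adherence(b)) - 1e-12)
    expect_lte(pooled, max(group_adherence(a), group_adherence(b)) + 1e-12)
  }
})

test_that("dumping 400 actuations into one window cannot push adherence past 1", {
  times <- as.POSIXct("2015-08-01 08:00:00", tz = "UTC") + seq_len(400) * 10
  ev <- ctrl_events(format(times, "%Y-%m-%d %H:%M:%S"))
  daily <- build_daily_records(ev, NULL, simple_regimen())
  expect_true(all(daily$am_adherence <= 1, na.rm = TRUE))
  expect_true(all(daily$daily_adherence <= 1, na.rm = TRUE))
  expect_equal(daily$am_taken[1], 400L)
  expect_equal(daily$daily_adherence[1], 0.5)  # AM capped at 1, PM missed
})

test_that("window counts conserve the in-range deduplicated event count", {
  withr::local_seed(23)
  for (rep in 1:25) {
    inst <- random_recount_instance()
    deduped <- deduplicate_events(inst$events, 60)
    w <- assign_windows(deduped, inst$regimen)
    in_range <- dplyr::inner_join(
      deduped[deduped$medication == "controller", ],
      inst$regimen, by = "participant_id") |>
      dplyr::filter(as.Date(timestamp, tz = "UTC") >= enrollment_date,
                    as.Date(timestamp, tz = "UTC") <= end_date)
    expect_equal(sum(w$am_count) + sum(w$pm_count), nrow(in_range))
  }
})

test_that("pipeline adherence equals a naive recount on random small cohorts", {
  withr::local_seed(31)
  for (rep in 1:150) {
    inst <- random_recount_instance()
    daily <- build_daily_records(inst$events, NULL, inst$regimen)
    expected <- oracle_recount(inst$events, inst$regimen)
    got <- tryCatch(group_adherence(daily), error = function(e) NA_real_)
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("the non-report comparison is flagged when every day is reported", {
  d <- make_daily(participant_id = "P1", study_day = 0:3,
                  daily_adherence = c(1, 0, 0.5, 0.5),
                  has_ema = TRUE, symptom_day = FALSE)
  cmp <- nonreport_vs_nonsymptom_comparison(d)
  expect_false(cmp$defined)
  expect_equal(cmp$n_nonreport, 0L)
})

test_that("the non-report comparison recovers a planted adherence gap", {
  d <- make_daily(participant_id = rep(c("A", "B"), each = 40),
                  study_day = rep(0:39, 2),
                  daily_adherence = c(rep(c(0.5, 1), 20), rep(c(0, 0.5), 20)),
                  has_ema = rep(c(TRUE, FALSE), 40),
                  symptom_day = rep(c(FALSE, NA), 40))
  cmp <- nonreport_vs_nonsymptom_comparison(d)
  expect_true(cmp$defined)
  expect_equal(cmp$mean_nonsymptom_report, mean(c(rep(0.5, 20), rep(0, 20))))
  expect_equal(cmp$mean_nonreport, mean(c(rep(1, 20), rep(0.5, 20))))
  expect_equal(cmp$difference,
               cmp$mean_nonsymptom_report - cmp$mean_nonreport)
})
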