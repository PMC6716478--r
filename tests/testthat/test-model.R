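test_that("model frames keep report days, and imputation only adds baseline days", {
  withr::local_seed(61)
  coh <- simulate_cohort(simulation_config(n_participants = 6, study_days = 60,
                                           seed = 61L))
  daily <- build_daily_records(coh$events, coh$ema, coh$regimen)
  fr_rep <- build_model_frame(daily, "report_days_only")
  fr_imp <- build_model_frame(daily, "impute_nonreport")
  n_def <- sum(!is.na(daily$daily_adherence))
  n_rep <- sum(!is.na(daily$daily_adherence) & daily$has_ema)
  expect_equal(nrow(fr_rep), n_rep)
  expect_equal(nrow(fr_imp), n_def)
  # imputed frame restricted to report days equals the report-only frame
  restr <- as.data.frame(fr_imp[fr_imp$has_ema, ])
  attr(restr, "mode") <- NULL
  ref <- as.data.frame(fr_rep)
  attr(ref, "mode") <- NULL
  expect_equal(restr, ref)
  # imputed non-report days sit at the reference anchors
  imp <- fr_imp[!fr_imp$has_ema, ]
  expect_true(all(imp$cough == 0 & imp$bored == 0))
  expect_true(all(imp$happy == 3 & imp$relaxed == 3))
  expect_true(all(!imp$any_symptom))
})

test_that("days with no prescribed doses are excluded in both modes", {
  daily <- make_daily(participant_id = "P1", study_day = 0:2,
                      daily_adherence = c(0.5, NA, 1),
                      has_ema = c(TRUE, TRUE, FALSE),
                      cough = c(0L, 1L, NA), wheeze = 0L, chest_tight = 0L,
                      stressed = 0L, angry = 0L, bored = 0L,
                      happy = 3L, relaxed = 3L,
                      symptom_day = c(FALSE, TRUE, NA))
  expect_equal(nrow(build_model_frame(daily, "report_days_only")), 1L)
  expect_equal(nrow(build_model_frame(daily, "impute_nonreport")), 2L)
})

test_that("reference anchors follow the questionnaire design", {
  fr <- simulate_model_frame(n_participants = 5, n_days = 10, item = "happy",
                             level_effects = c(5, 0, 0, 0))
  est <- fit_adherence_model(fr, "happy")
  expect_equal(unique(est$reference_level), "3")
  expect_equal(est$effect[est$level == "3"], 0)
  fr2 <- simulate_model_frame(n_participants = 5, n_days = 10, item = "cough",
                              level_effects = c(0, 5, 5, 5))
  est2 <- fit_adherence_model(fr2, "cough")
  expect_equal(unique(est2$reference_level), "0")
})

test_that("never-observed levels are reported as N/A rows, not dropped", {
  withr::local_seed(71)
  fr <- simulate_model_frame(n_participants = 8, n_days = 20, item = "wheeze",
                             level_effects = c(0, 2, 0, 0),
                             level_probs = c(0.8, 0.2, 0, 0))
  est <- fit_adherence_model(fr, "wheeze")
  expect_equal(nrow(est), 4L)
  expect_true(all(est$na_flag[est$level %in% c("2", "3")]))
  expect_false(any(est$na_flag[est$level %in% c("0", "1")]))
})

test_that("single-participant frames and flat outcomes are diagnostic errors", {
  fr <- simulate_model_frame(n_participants = 1, n_days = 10)
  expect_error(fit_adherence_model(fr, "bored"), "2 participants",
               class = "adhema_model_error")
  fr2 <- simulate_model_frame(n_participants = 4, n_days = 10,
                              ranef_sd = 0, resid_sd = 0,
                              level_effects = c(0, 0, 0, 0))
  expect_error(fit_adherence_model(fr2, "bored"), "bored",
               class = "adhema_model_error")
})

test_that("relabelling participants leaves estimates unchanged", {
  withr::local_seed(83)
  fr <- simulate_model_frame(n_participants = 10, n_days = 20)
  est1 <- fit_adherence_model(fr, "bored")
  fr2 <- fr
  map <- setNames(sprintf("Z%02d", sample(10)), unique(fr$participant_id))
  fr2$participant_id <- unname(map[fr$participant_id])
  est2 <- fit_adherence_model(fr2, "bored")
  expect_equal(est1$effect, est2$effect, tolerance = 1e-8)
  expect_equal(est1$ci_low, est2$ci_low, tolerance = 1e-8)
})

test_that("shifting every outcome by a constant moves only the intercept", {
  withr::local_seed(89)
  fr <- simulate_model_frame(n_participants = 10, n_days = 20)
  est1 <- fit_adherence_model(fr, "bored")
  fr2 <- fr
  fr2$adherence_pct <- fr2$adherence_pct + 17
  est2 <- fit_adherence_model(fr2, "bored")
  expect_equal(est1$effect, est2$effect, tolerance = 1e-7)
  expect_equal(est1$p_value, est2$p_value, tolerance = 1e-6)
})

test_that("with no between-participant variance the fit matches pooled OLS", {
  withr::local_seed(97)
  fr <- simulate_model_frame(n_participants = 12, n_days = 30, ranef_sd = 0)
  est <- suppressMessages(fit_adherence_model(fr, "bored"))
  ols <- lm(adherence_pct ~ study_day + factor(bored), data = fr)
  for (lv in c("1", "2", "3")) {
    expect_equal(est$effect[est$level == lv],
                 unname(coef(ols)[paste0("factor(bored)", lv)]),
                 tolerance = 1e-4)
  }
})

test_that("a planted effect is recovered within its interval", {
  withr::local_seed(101)
  fr <- simulate_model_frame(n_participants = 30, n_days = 60,
                             level_effects = c(0, 0, 0, 20))
  est <- fit_adherence_model(fr, "bored")
  row <- est[est$level == "3", ]
  expect_true(row$ci_low <= 20 && 20 <= row$ci_high)
  expect_true(all(est$ci_low <= est$effect & est$effect <= est$ci_high,
                  na.rm = TRUE))
})

test_that("the any-symptom model uses the binary indicator", {
  withr::local_seed(103)
  coh <- simulate_cohort(simulation_config(n_participants = 10, study_days = 60,
                                           ema_report_prob = 0.8,
                                           episode_hazard = 0.05, seed = 103L))
  daily <- build_daily_records(coh$events, coh$ema, coh$regimen)
  fr <- build_model_frame(daily, "report_days_only")
  est <- fit_adherence_model(fr, "any_symptom")
  expect_equal(nrow(est), 2L)
  expect_equal(est$level, c("FALSE", "TRUE"))
  expect_true(est$is_reference[1])
})

test_that("sensitivity comparison of identical estimates is all-zero, unflagged", {
  withr::local_seed(107)
  fr <- simulate_model_frame(n_participants = 8, n_days = 15)
  est <- fit_adherence_model(fr, "bored")
  cmp <- sensitivity_compare(est, est)
  expect_true(all(cmp$difference == 0, na.rm = TRUE))
  expect_false(any(cmp$flag))
})

test_that("fit_all_items reports per-item failures without aborting the batch", {
  withr::local_seed(109)
  fr <- simulate_model_frame(n_participants = 6, n_days = 12)
  # only `bored` carries data in this harness frame; others are all-NA
  est <- fit_all_items(fr, items = c("bored", "wheeze"))
  expect_true("bored" %in% est$item)
  errs <- attr(est, "model_errors")
  expect_true("wheeze" %in% names(errs))
})
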