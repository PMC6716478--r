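# 12-hour-window controller adherence.
#
# Adherence is computed per half-day window — AM = [00:00, 12:00), PM =
# [12:00, 24:00) local clock time — as min(taken, prescribed) / prescribed.
# Capping taken at prescribed per window is the guard against overdosing and
# medication dumping: firing the inhaler many times in one window can never
# raise that window's adherence above 1, nor compensate for a missed window.

#' Bin controller actuations into AM/PM windows per study day
#'
#' Counts deduplicated controller actuations per participant-day into the AM
#' window `[00:00, 12:00)` and the PM window `[12:00, 24:00)` (half-open:
#' 11:59 is AM, 12:00 exactly is PM). Events dated before enrollment or
#' after the study end date are excluded and logged in the `"discard_log"`
#' attribute.
#'
#' @param events Deduplicated event tibble; non-controller rows are ignored.
#' @param regimen Regimen tibble from [read_regimen()].
#' @return Tibble with `participant_id`, `date`, `study_day`, `am_count`,
#'   `pm_count` for participant-days with at least one in-range controller
#'   actuation.
#' @export
assign_windows <- function(events, regimen) {
  ev <- dplyr::filter(events, .data$medication == "controller")
  ev <- dplyr::inner_join(ev, regimen, by = "participant_id")
  ev$date <- civil_date(ev$timestamp)
  in_range <- ev$date >= ev$enrollment_date & ev$date <= ev$end_date
  discarded <- ev[!in_range, c("participant_id", "timestamp", "medication")]
  ev <- ev[in_range, , drop = FALSE]
  ev$study_day <- as.integer(ev$date - ev$enrollment_date)
  ev$is_am <- civil_hour(ev$timestamp) < 12L
  out <- ev |>
    dplyr::group_by(.data$participant_id, .data$date, .data$study_day) |>
    dplyr::summarise(am_count = sum(.data$is_am),
                     pm_count = sum(!.data$is_am),
                     .groups = "drop")
  attr(out, "discard_log") <- tibble::as_tibble(discarded)
  out
}

#' Capped single-window adherence
#'
#' `min(taken, prescribed) / prescribed`, or `NA` when nothing is prescribed
#' in the window. The cap means extra actuations in a window (overdosing,
#' dumping) never inflate adherence.
#'
#' @param taken,prescribed Non-negative integer vectors (recycled).
#' @return Numeric vector of fractions in `[0, 1]`, `NA` where
#'   `prescribed == 0`.
#' @export
#' @examples
#' window_adherence(c(1, 3, 1, 2), c(1, 1, 2, 0))
window_adherence <- function(taken, prescribed) {
  if (any(taken < 0, na.rm = TRUE) || any(prescribed < 0, na.rm = TRUE)) {
    abort("`taken` and `prescribed` must be non-negative.")
  }
  out <- pmin(taken, prescribed) / prescribed
  out[prescribed == 0] <- NA_real_
  out
}

#' Daily adherence from the two window adherences
#'
#' The mean of the defined window adherences (windows with at least one
#' prescribed dose); `NA` when neither window carries a prescription.
#' Averaging windows — rather than pooling doses over the day — preserves
#' the per-window dumping guard: an AM double-dose cannot mask a missed PM
#' dose.
#'
#' @param am_taken,pm_taken Actuation counts per window.
#' @param am_doses,pm_doses Prescribed doses per window.
#' @return Numeric vector of daily adherence fractions.
#' @export
daily_adherence <- function(am_taken, pm_taken, am_doses, pm_doses) {
  am <- window_adherence(am_taken, am_doses)
  pm <- window_adherence(pm_taken, pm_doses)
  out <- rowMeans(cbind(am, pm), na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Assemble the participant-day analysis table
#'
#' The central constructor: deduplicates events, bins controller actuations
#' into half-day windows, merges same-day EMA reports (per-item maximum),
#' classifies asthma-symptom days, and returns one row per participant-day
#' from enrollment (study day 0) through the study end date.
#'
#' @param events Event tibble from [read_events()] (deduplication is applied
#'   internally with the configured tolerance).
#' @param ema EMA tibble from [read_ema()]; may have zero rows.
#' @param regimen Regimen tibble from [read_regimen()].
#' @param config A [study_config()].
#' @return Tibble with columns `participant_id, study_day, date, am_taken,
#'   pm_taken, am_adherence, pm_adherence, daily_adherence, has_ema,
#'   has_any_data, symptom_day` and one integer column per EMA item
#'   (same-day reports merged by per-item maximum). `symptom_day` is `NA`
#'   on days without a report — absence of a report is never evidence of
#'   absence of symptoms.
#' @export
build_daily_records <- function(events, ema, regimen, config = study_config()) {
  deduped <- deduplicate_events(events, config$dedup_tolerance_minutes)

  grid <- regimen |>
    dplyr::rowwise() |>
    dplyr::reframe(
      participant_id = .data$participant_id,
      date = seq(.data$enrollment_date, .data$end_date, by = "day"),
      am_doses = .data$am_doses, pm_doses = .data$pm_doses
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(study_day = as.integer(.data$date - min(.data$date))) |>
    dplyr::ungroup()
  if (!config$include_enrollment_day) {
    grid <- dplyr::filter(grid, .data$study_day > 0L)
  }

  ctrl <- assign_windows(deduped, regimen)

  # any in-range actuation (controller or rescue) counts as device data
  anyev <- dplyr::inner_join(deduped, regimen, by = "participant_id")
  anyev$date <- civil_date(anyev$timestamp)
  anyev <- anyev |>
    dplyr::filter(.data$date >= .data$enrollment_date, .data$date <= .data$end_date) |>
    dplyr::distinct(.data$participant_id, .data$date) |>
    dplyr::mutate(has_event = TRUE)

  ema_daily <- merge_ema_days(ema, config)

  daily <- grid |>
    dplyr::left_join(ctrl[, c("participant_id", "date", "am_count", "pm_count")],
                     by = c("participant_id", "date")) |>
    dplyr::left_join(anyev, by = c("participant_id", "date")) |>
    dplyr::left_join(ema_daily, by = c("participant_id", "date")) |>
    dplyr::mutate(
      am_taken = as.integer(dplyr::coalesce(.data$am_count, 0L)),
      pm_taken = as.integer(dplyr::coalesce(.data$pm_count, 0L)),
      am_adherence = window_adherence(.data$am_taken, .data$am_doses),
      pm_adherence = window_adherence(.data$pm_taken, .data$pm_doses),
      daily_adherence = daily_adherence(.data$am_taken, .data$pm_taken,
                                        .data$am_doses, .data$pm_doses),
      has_ema = dplyr::coalesce(.data$has_ema, FALSE),
      has_any_data = .data$has_ema | dplyr::coalesce(.data$has_event, FALSE),
      symptom_day = dplyr::if_else(.data$has_ema, .data$symptom_day, NA)
    ) |>
    dplyr::select(dplyr::all_of(c(
      "participant_id", "study_day", "date", "am_taken", "pm_taken",
      "am_adherence", "pm_adherence", "daily_adherence",
      "has_ema", "has_any_data", "symptom_day", EMA_ITEMS
    ))) |>
    dplyr::arrange(.data$participant_id, .data$study_day)

  attr(daily, "dedup_log") <- attr(deduped, "dedup_log")
  attr(daily, "discard_log") <- attr(ctrl, "discard_log")
  daily
}

# Merge same-day EMA reports to one row per participant-day: per-item
# maximum across reports, symptom_day from the configured threshold.
merge_ema_days <- function(ema, config = study_config()) {
  if (is.null(ema) || nrow(ema) == 0L) {
    return(tibble::as_tibble(c(
      list(participant_id = character(), date = as.Date(character()),
           has_ema = logical(), symptom_day = logical()),
      setNames(rep(list(integer()), length(EMA_ITEMS)), EMA_ITEMS)
    )))
  }
  ema$date <- civil_date(ema$timestamp)
  max_or_na <- function(x) if (all(is.na(x))) NA_integer_ else as.integer(max(x, na.rm = TRUE))
  merged <- ema |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(EMA_ITEMS), max_or_na),
                     .groups = "drop")
  thr <- config$symptom_threshold
  sym <- merged[, SYMPTOM_ITEMS, drop = FALSE] >= thr
  merged$symptom_day <- apply(sym, 1L, function(z) isTRUE(any(z, na.rm = TRUE)))
  merged$has_ema <- TRUE
  merged[, c("participant_id", "date", "has_ema", "symptom_day", EMA_ITEMS)]
}

#' Cohort (group) adherence
#'
#' The unweighted mean of daily adherence over every participant-day on
#' which daily adherence is defined.
#'
#' @param daily Daily-record tibble from [build_daily_records()].
#' @return A single fraction in `[0, 1]`.
#' @export
group_adherence <- function(daily) {
  x <- daily$daily_adherence
  x <- x[!is.na(x)]
  if (!length(x)) {
    abort("No participant-days with defined daily adherence.",
          class = "adhema_empty_error")
  }
  mean(x)
}

#' Compare adherence on non-symptom-report days vs non-report days
#'
#' Splits participant-days with defined adherence into days with an EMA
#' report showing no asthma symptoms versus days with no report at all, and
#' contrasts their mean daily adherence with a Welch two-sample t-test. A
#' lower non-report mean is the signature of informative missingness:
#' participants not reporting on exactly the days they also skip doses.
#'
#' @param daily Daily-record tibble.
#' @return List with `defined` (logical), the two group means (fractions),
#'   `difference` (non-symptom minus non-report), `p_value`, and group
#'   sizes. When either group has fewer than 2 days the comparison is
#'   flagged undefined.
#' @export
nonreport_vs_nonsymptom_comparison <- function(daily) {
  ok <- !is.na(daily$daily_adherence)
  nonsym <- daily$daily_adherence[ok & daily$has_ema & !is.na(daily$symptom_day) &
                                    !daily$symptom_day]
  nonrep <- daily$daily_adherence[ok & !daily$has_ema]
  if (length(nonsym) < 2L || length(nonrep) < 2L) {
    return(list(defined = FALSE,
                mean_nonsymptom_report = if (length(nonsym)) mean(nonsym) else NA_real_,
                mean_nonreport = if (length(nonrep)) mean(nonrep) else NA_real_,
                difference = NA_real_, p_value = NA_real_,
                n_nonsymptom = length(nonsym), n_nonreport = length(nonrep),
                note = "one comparison group is empty or has a single day"))
  }
  tt <- t.test(nonsym, nonrep)
  list(defined = TRUE,
       mean_nonsymptom_report = mean(nonsym),
       mean_nonreport = mean(nonrep),
       difference = mean(nonsym) - mean(nonrep),
       p_value = tt$p.value,
       n_nonsymptom = length(nonsym), n_nonreport = length(nonrep))
}
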