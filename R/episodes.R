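# Asthma-symptom-day classification and new-episode detection.
#
# A day is an asthma-symptom day when any report that day endorses cough,
# wheeze or chest tightness at or above the configured threshold (default
# "A little"). A new symptom episode opens at a symptom report that (1)
# falls at least `initial_exacerbation_days` (default 7) days
# post-enrollment and (2) is separated from any earlier symptoms by at
# least one intervening non-symptom report. Symptoms reported contiguously
# from enrollment form the initial exacerbation, which is never counted as
# a new episode; a first-ever report that is already symptomatic at day >= 7
# has indeterminate onset and opens nothing.

#' Classify asthma-symptom days from EMA reports
#'
#' Merges same-day reports per participant (per-item maximum) and flags a
#' day as a symptom day when cough, wheeze or chest tightness reaches the
#' configured Likert threshold. Days without a report carry no flag at all:
#' they are absent from the output, never `FALSE`.
#'
#' @param ema EMA tibble from [read_ema()].
#' @param config A [study_config()].
#' @return Tibble `participant_id, date, symptom_day` with one row per
#'   participant-day that has at least one report.
#' @export
classify_symptom_days <- function(ema, config = study_config()) {
  merged <- merge_ema_days(ema, config)
  merged[, c("participant_id", "date", "symptom_day")]
}

# Core scan over one participant's report days, in study-day order.
# `symptom` may contain NA (a report with all symptom items missing counts
# as a non-symptom report only if some level is recorded; here NA-only
# symptom items were already resolved to FALSE upstream).
episode_scan <- function(study_day, symptom, min_day = 7L) {
  ord <- order(study_day)
  study_day <- as.integer(study_day[ord])
  symptom <- as.logical(symptom[ord])
  starts <- integer(0)
  init_end <- NA_integer_
  indeterminate <- FALSE
  any_report <- FALSE
  cleared <- FALSE     # a non-symptom report seen since the last symptom
  in_initial <- FALSE  # inside the enrollment-contiguous symptom run
  for (i in seq_along(study_day)) {
    d <- study_day[i]
    if (isTRUE(symptom[i])) {
      if (!any_report) {
        if (d < min_day) {
          in_initial <- TRUE
          init_end <- d
        } else {
          indeterminate <- TRUE  # symptomatic first contact, onset unknown
        }
      } else if (in_initial && !cleared) {
        init_end <- d            # initial exacerbation continues
      } else if (cleared && d >= min_day) {
        starts <- c(starts, d)   # both episode criteria met
      }
      # cleared == FALSE and not initial: continuation of the current run
      cleared <- FALSE
    } else {
      cleared <- TRUE
      in_initial <- FALSE
    }
    any_report <- TRUE
  }
  list(initial_exacerbation_end = init_end,
       episode_start_days = starts,
       episode_count = length(starts),
       indeterminate_onset = indeterminate)
}

#' Detect new asthma-symptom episodes for one participant
#'
#' Applies the two-criterion episode rule to a participant's sequence of
#' report-day symptom flags: an episode starts at a symptom report on study
#' day `>= initial_exacerbation_days` that is preceded, since the most
#' recent earlier symptom report (or since enrollment), by at least one
#' non-symptom report. Consecutive symptom reports with no intervening
#' non-symptom report belong to the same episode. The enrollment-contiguous
#' symptom run (starting before the day threshold) is returned as the
#' initial exacerbation, not an episode.
#'
#' @param study_day Integer vector of study days on which a report exists.
#' @param symptom Logical vector, same length: was that report day a
#'   symptom day?
#' @param config A [study_config()] (supplies the day threshold).
#' @return List with `initial_exacerbation_end` (last study day of the
#'   enrollment-contiguous run, or `NA`), `episode_start_days` (strictly
#'   increasing integer vector), `episode_count`, and
#'   `indeterminate_onset` (`TRUE` when the first-ever report was already
#'   symptomatic at or past the threshold, so onset cannot be placed).
#' @export
#' @examples
#' detect_new_episodes(c(0, 1, 5, 10), c(TRUE, TRUE, FALSE, TRUE))
detect_new_episodes <- function(study_day, symptom, config = study_config()) {
  stopifnot(length(study_day) == length(symptom))
  episode_scan(study_day, symptom, min_day = config$initial_exacerbation_days)
}

#' Detect episodes for every participant in a daily table
#'
#' @param daily Daily-record tibble from [build_daily_records()].
#' @param config A [study_config()].
#' @return Tibble with one row per participant: `participant_id`,
#'   `episode_count`, `initial_exacerbation_end`, `indeterminate_onset`,
#'   and a list-column `episode_start_days`.
#' @export
cohort_episodes <- function(daily, config = study_config()) {
  daily |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      rep_rows <- df[df$has_ema & !is.na(df$symptom_day), , drop = FALSE]
      res <- episode_scan(rep_rows$study_day, rep_rows$symptom_day,
                          min_day = config$initial_exacerbation_days)
      tibble::tibble(
        episode_count = res$episode_count,
        initial_exacerbation_end = res$initial_exacerbation_end,
        indeterminate_onset = res$indeterminate_onset,
        episode_start_days = list(res$episode_start_days)
      )
    }) |>
    dplyr::ungroup()
}
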