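#' Analysis configuration
#'
#' Bundles the small number of tunable rules used across the pipeline: the
#' time tolerance for matching a manual medication entry to the device record
#' of the same actuation, the Likert level at or above which a symptom item
#' counts as endorsed, and the minimum study day for a symptom run to qualify
#' as a new episode rather than the enrollment-contiguous initial
#' exacerbation.
#'
#' @param dedup_tolerance_minutes Positive number. A manual entry is treated
#'   as a duplicate of a device actuation of the same medication when their
#'   timestamps differ by at most this many minutes. Default 60.
#' @param symptom_threshold Likert level in `1:3`. A day is an asthma-symptom
#'   day when any of cough, wheeze or chest tightness is reported at or above
#'   this level. Default 1 ("A little").
#' @param initial_exacerbation_days Integer number of days post-enrollment a
#'   symptom report must reach before it can open a new symptom episode.
#'   Default 7.
#' @param include_enrollment_day Logical; keep study day 0 in adherence and
#'   acquisition denominators. Default `TRUE`.
#' @param verbose Logical; emit progress messages from pipeline stages.
#'
#' @return A list of class `"adhema_config"`.
#' @export
#' @examples
#' study_config(dedup_tolerance_minutes = 30)
study_config <- function(dedup_tolerance_minutes = 60,
                         symptom_threshold = 1,
                         initial_exacerbation_days = 7,
                         include_enrollment_day = TRUE,
                         verbose = FALSE) {
  if (!is.numeric(dedup_tolerance_minutes) || length(dedup_tolerance_minutes) != 1 ||
      is.na(dedup_tolerance_minutes) || dedup_tolerance_minutes <= 0) {
    abort("`dedup_tolerance_minutes` must be a single positive number.")
  }
  if (!symptom_threshold %in% 1:3) {
    abort("`symptom_threshold` must be 1, 2 or 3.")
  }
  if (!is.numeric(initial_exacerbation_days) || initial_exacerbation_days < 0) {
    abort("`initial_exacerbation_days` must be a non-negative integer.")
  }
  structure(
    list(
      dedup_tolerance_minutes = dedup_tolerance_minutes,
      symptom_threshold = as.integer(symptom_threshold),
      initial_exacerbation_days = as.integer(initial_exacerbation_days),
      include_enrollment_day = isTRUE(include_enrollment_day),
      likert_labels = LIKERT_LABELS,
      verbose = isTRUE(verbose)
    ),
    class = "adhema_config"
  )
}

#' @export
print.adhema_config <- function(x, ...) {
  cat("<adhema_config>\n")
  cat("  dedup tolerance:", x$dedup_tolerance_minutes, "min\n")
  cat("  symptom threshold: Likert >=", x$symptom_threshold,
      sprintf("(%s)", x$likert_labels[x$symptom_threshold + 1]), "\n")
  cat("  episode threshold: day >=", x$initial_exacerbation_days, "\n")
  invisible(x)
}
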