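# Data-acquisition outcomes: how often did monitoring yield anything at all?
# The fraction of participant-days with any asthma data (inhaler actuation
# or EMA report) is the feasibility signal; the EMA-only fraction tracks
# active engagement with the questionnaire.

#' Data-acquisition summary
#'
#' Computes, over all participant-days, the count and fraction of days with
#' any data (actuation or EMA) and with an EMA report, plus the same
#' fractions per participant. When the cohort is partitioned into
#' participants enrolled before and after a platform redesign, the
#' per-participant percent-of-days values are compared between the two
#' enrollee groups with Welch t-tests.
#'
#' @param daily Daily-record tibble from [build_daily_records()].
#' @param post_redesign_ids Optional character vector of participant ids
#'   enrolled after the redesign; the rest form the pre-redesign group.
#' @return List of class `"adhema_acquisition"`: `total_days`,
#'   `any_data_days`, `any_data_fraction`, `ema_days`, `ema_fraction`,
#'   `per_participant` (tibble), and `redesign` (NULL or the two group
#'   means with t-test p-values for both metrics).
#' @export
acquisition_metrics <- function(daily, post_redesign_ids = NULL) {
  per <- daily |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      any_data_fraction = mean(.data$has_any_data),
      ema_fraction = mean(.data$has_ema),
      .groups = "drop"
    )
  out <- list(
    total_days = nrow(daily),
    any_data_days = sum(daily$has_any_data),
    any_data_fraction = mean(daily$has_any_data),
    ema_days = sum(daily$has_ema),
    ema_fraction = mean(daily$has_ema),
    per_participant = per,
    redesign = NULL
  )
  if (!is.null(post_redesign_ids)) {
    post <- per$participant_id %in% post_redesign_ids
    if (sum(post) >= 2L && sum(!post) >= 2L) {
      t_any <- t.test(per$any_data_fraction[post], per$any_data_fraction[!post])
      t_ema <- t.test(per$ema_fraction[post], per$ema_fraction[!post])
      out$redesign <- list(
        pre_any_data = mean(per$any_data_fraction[!post]),
        post_any_data = mean(per$any_data_fraction[post]),
        p_any_data = t_any$p.value,
        pre_ema = mean(per$ema_fraction[!post]),
        post_ema = mean(per$ema_fraction[post]),
        p_ema = t_ema$p.value
      )
    } else {
      out$redesign <- list(note = "fewer than 2 participants in a redesign group")
    }
  }
  class(out) <- "adhema_acquisition"
  out
}

#' @export
print.adhema_acquisition <- function(x, ...) {
  cat(sprintf("Any asthma data on %d/%d participant-days (%.1f%%)\n",
              x$any_data_days, x$total_days, 100 * x$any_data_fraction))
  cat(sprintf("EMA report on %d/%d participant-days (%.1f%%)\n",
              x$ema_days, x$total_days, 100 * x$ema_fraction))
  invisible(x)
}

#' EMA reporting frequency by age, gender, and weekend vs weekday
#'
#' Per-participant EMA reporting fractions are related to age (Pearson
#' correlation), gender (Welch t-test of the two group means), and day type
#' (paired t-test of each participant's weekend fraction against their
#' weekday fraction; weekend = Saturday/Sunday).
#'
#' @param daily Daily-record tibble.
#' @param demographics Tibble with `participant_id`, `age` (years, numeric)
#'   and `gender` (two levels, e.g. "female"/"male").
#' @return List with components `age` (r, p), `gender` (group means, p) and
#'   `weekend` (mean weekend/weekday fractions, p). Degenerate inputs (zero
#'   variance, a single-gender cohort) return `NA` statistics with a note
#'   rather than an error.
#' @export
reporting_subgroup_tests <- function(daily, demographics) {
  per <- daily |>
    dplyr::mutate(weekend = format(.data$date, "%u") %in% c("6", "7")) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      ema_fraction = mean(.data$has_ema),
      weekend_fraction = if (any(.data$weekend)) mean(.data$has_ema[.data$weekend]) else NA_real_,
      weekday_fraction = if (any(!.data$weekend)) mean(.data$has_ema[!.data$weekend]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::inner_join(demographics, by = "participant_id")

  age <- if (nrow(per) >= 3L && sd(per$ema_fraction) > 0 && sd(per$age) > 0) {
    ct <- cor.test(per$age, per$ema_fraction)
    list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(per))
  } else {
    list(r = NA_real_, p_value = NA_real_, n = nrow(per),
         note = "constant reporting fraction or age; correlation undefined")
  }

  sexes <- unique(per$gender)
  gender <- if (length(sexes) == 2L &&
                all(table(per$gender) >= 2L) &&
                sd(per$ema_fraction) > 0) {
    g1 <- per$ema_fraction[per$gender == sexes[1]]
    g2 <- per$ema_fraction[per$gender == sexes[2]]
    if (sd(g1) > 0 || sd(g2) > 0) {
      tt <- t.test(g1, g2)
      stats::setNames(
        list(mean(g1), mean(g2), tt$p.value, nrow(per)),
        c(paste0("mean_", sexes[1]), paste0("mean_", sexes[2]), "p_value", "n"))
    } else {
      list(p_value = NA_real_, note = "zero within-group variance")
    }
  } else {
    list(p_value = NA_real_, note = "gender comparison undefined for this cohort")
  }

  pairs <- per[!is.na(per$weekend_fraction) & !is.na(per$weekday_fraction), ]
  diffs <- pairs$weekend_fraction - pairs$weekday_fraction
  weekend <- if (nrow(pairs) >= 2L && sd(diffs) > 0) {
    tt <- t.test(pairs$weekend_fraction, pairs$weekday_fraction, paired = TRUE)
    list(mean_weekend = mean(pairs$weekend_fraction),
         mean_weekday = mean(pairs$weekday_fraction),
         p_value = tt$p.value, n = nrow(pairs))
  } else {
    list(mean_weekend = if (nrow(pairs)) mean(pairs$weekend_fraction) else NA_real_,
         mean_weekday = if (nrow(pairs)) mean(pairs$weekday_fraction) else NA_real_,
         p_value = NA_real_, n = nrow(pairs),
         note = "no variation in weekend-weekday difference")
  }

  list(age = age, gender = gender, weekend = weekend, per_participant = per)
}
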