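# End-to-end orchestration: dedup -> windows -> adherence -> symptoms ->
# episodes -> acquisition -> models, with stage logging and graceful
# degradation when the model stage cannot run (e.g. no EMA data at all).

#' Run the full analysis pipeline
#'
#' Executes every stage in fixed order on validated input tables and
#' collects the cohort summary: group adherence, data-acquisition metrics,
#' per-participant episode detections, the non-report vs non-symptom
#' adherence comparison, and the per-item mixed-model estimates in one or
#' both analysis modes (report days only; non-report days imputed at
#' reference). Model-stage failures never abort the pipeline: affected
#' items are flagged in `model_errors` and all other sections are still
#' produced.
#'
#' @param events,ema,regimen Input tibbles from [read_events()],
#'   [read_ema()], [read_regimen()] (or a simulated cohort's components).
#' @param config A [study_config()].
#' @param demographics Optional tibble for [reporting_subgroup_tests()].
#' @param post_redesign_ids Optional participant partition for the
#'   redesign comparison in [acquisition_metrics()].
#' @param modes Which model frames to fit.
#' @return List of class `"adhema_result"`.
#' @export
run_pipeline <- function(events, ema, regimen, config = study_config(),
                         demographics = NULL, post_redesign_ids = NULL,
                         modes = c("report_days_only", "impute_nonreport")) {
  modes <- match.arg(modes, several.ok = TRUE)
  say <- function(...) if (config$verbose) inform(sprintf(...))

  daily <- build_daily_records(events, ema, regimen, config)
  say("daily table: %d participant-days", nrow(daily))

  adh <- tryCatch(group_adherence(daily), error = function(e) NA_real_)
  acq <- acquisition_metrics(daily, post_redesign_ids)
  eps <- cohort_episodes(daily, config)
  cmp <- nonreport_vs_nonsymptom_comparison(daily)

  estimates <- list(); model_errors <- list(); sensitivity <- NULL
  if (sum(daily$has_ema) == 0L) {
    model_errors$all <- "no EMA reports: symptom/episode/model sections are empty"
  } else {
    for (m in modes) {
      frame <- build_model_frame(daily, m)
      est <- fit_all_items(frame)
      estimates[[m]] <- est
      errs <- attr(est, "model_errors")
      if (length(errs)) model_errors[[m]] <- errs
    }
    if (all(c("report_days_only", "impute_nonreport") %in% names(estimates))) {
      sensitivity <- sensitivity_compare(estimates$report_days_only,
                                         estimates$impute_nonreport)
    }
  }

  subgroups <- if (!is.null(demographics)) {
    reporting_subgroup_tests(daily, demographics)
  }

  structure(
    list(
      n_participants = nrow(regimen),
      n_days = nrow(daily),
      group_adherence = adh,
      acquisition = acq,
      episodes = eps,
      episode_total = sum(eps$episode_count),
      comparison = cmp,
      estimates = estimates,
      sensitivity = sensitivity,
      subgroups = subgroups,
      model_errors = model_errors,
      daily = daily,
      provenance = list(
        config = unclass(config),
        input_hash = rlang::hash(list(events, ema, regimen)),
        n_events = nrow(events), n_ema = nrow(ema)
      )
    ),
    class = "adhema_result"
  )
}

#' @export
print.adhema_result <- function(x, ...) {
  cat(sprintf("<adhema_result> %d participants, %d participant-days\n",
              x$n_participants, x$n_days))
  cat(sprintf("  group adherence: %.1f%%\n", 100 * x$group_adherence))
  cat(sprintf("  any-data days: %.1f%%; EMA days: %.1f%%\n",
              100 * x$acquisition$any_data_fraction,
              100 * x$acquisition$ema_fraction))
  cat(sprintf("  new symptom episodes: %d\n", x$episode_total))
  invisible(x)
}

# Plain-list (JSON-ready) view of a pipeline result.
result_to_list <- function(result) {
  est <- lapply(result$estimates, function(e) as.data.frame(e))
  list(
    n_participants = result$n_participants,
    n_days = result$n_days,
    group_adherence = result$group_adherence,
    acquisition = list(
      total_days = result$acquisition$total_days,
      any_data_days = result$acquisition$any_data_days,
      any_data_fraction = result$acquisition$any_data_fraction,
      ema_days = result$acquisition$ema_days,
      ema_fraction = result$acquisition$ema_fraction
    ),
    episode_total = result$episode_total,
    episodes = as.data.frame(
      dplyr::mutate(result$episodes, episode_start_days = vapply(
        .data$episode_start_days, paste, character(1), collapse = ";"))),
    comparison = result$comparison,
    estimates = est,
    model_errors = lapply(result$model_errors, function(e) unlist(e))
  )
}

fmt_pct <- function(x, digits = 1) {
  ifelse(is.na(x), "N/A", sprintf(paste0("%+.", digits, "f%%"), x))
}

#' Render a pipeline result as JSON or markdown
#'
#' JSON output is a stable machine-readable document that round-trips
#' through [parse_report()]; markdown output is a human-readable summary
#' whose estimates table mirrors the conventional presentation: one row
#' per questionnaire item, one column per Likert level, `Reference` for
#' the anchor level and `N/A` for levels never observed.
#'
#' @param result An `"adhema_result"` from [run_pipeline()].
#' @param format `"json"` or `"markdown"`.
#' @return A single string.
#' @export
render_report <- function(result, format = c("json", "markdown")) {
  format <- match.arg(format)
  lst <- result_to_list(result)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = 10,
                                         na = "null", pretty = TRUE)))
  }
  lines <- c(
    "# Cohort monitoring report", "",
    sprintf("- Participants: %d", lst$n_participants),
    sprintf("- Participant-days: %d", lst$n_days),
    sprintf("- Group adherence: %.1f%%", 100 * lst$group_adherence),
    sprintf("- Any asthma data: %d/%d days (%.1f%%)",
            lst$acquisition$any_data_days, lst$acquisition$total_days,
            100 * lst$acquisition$any_data_fraction),
    sprintf("- EMA reports: %d/%d days (%.1f%%)",
            lst$acquisition$ema_days, lst$acquisition$total_days,
            100 * lst$acquisition$ema_fraction),
    sprintf("- New asthma symptom episodes: %d", lst$episode_total),
    ""
  )
  if (isTRUE(lst$comparison$defined)) {
    lines <- c(lines, sprintf(
      "Adherence on non-symptom report days vs non-report days: %.1f%% vs %.1f%% (P=%.3g)",
      100 * lst$comparison$mean_nonsymptom_report,
      100 * lst$comparison$mean_nonreport, lst$comparison$p_value), "")
  } else {
    lines <- c(lines,
               "Non-report vs non-symptom comparison undefined for these data.", "")
  }
  for (m in names(lst$estimates)) {
    est <- lst$estimates[[m]]
    if (!nrow(est)) next
    lines <- c(lines, sprintf("## Adherence model estimates (%s)", m), "",
               "| Item | Not at all | A little | A lot | Extremely |",
               "|------|-----------|----------|-------|-----------|")
    for (it in unique(est$item)) {
      sub <- est[est$item == it, ]
      cells <- vapply(as.character(if (it == "any_symptom") c(FALSE, TRUE) else 0:3),
                      function(lv) {
        row <- sub[sub$level == lv, ]
        if (!nrow(row)) return("N/A")
        if (row$is_reference) return("Reference")
        if (row$na_flag) return("N/A")
        sprintf("%s (%s to %s)", fmt_pct(row$effect),
                fmt_pct(row$ci_low), fmt_pct(row$ci_high))
      }, character(1))
      if (it == "any_symptom") cells <- c(cells, "N/A", "N/A")
      lines <- c(lines, paste0("| ", it, " | ", paste(cells, collapse = " | "), " |"))
    }
    lines <- c(lines, "")
  }
  if (!length(lst$estimates)) {
    lines <- c(lines, "## Adherence model estimates", "",
               "Model section empty: no EMA data available.", "")
  }
  if (length(lst$model_errors)) {
    lines <- c(lines, "## Model-stage notes", "",
               unlist(lapply(names(lst$model_errors), function(k) {
                 sprintf("- %s: %s", k, paste(lst$model_errors[[k]], collapse = "; "))
               })), "")
  }
  paste(lines, collapse = "\n")
}

#' @rdname render_report
#' @param json A JSON report string from `render_report(..., "json")`.
#' @export
parse_report <- function(json) {
  jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
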