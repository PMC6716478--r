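# Independent oracles, written directly from the definitions and kept free
# of any code shared with the implementation they check.

# --- dedup oracle: exhaustive optimal matching -------------------------------
# Enumerates every injective device -> manual assignment within tolerance
# (per participant x medication), keeps the assignments with the most pairs
# and, among those, minimal total |gap|; returns the surviving event rows.
oracle_dedup <- function(events, tolerance_minutes) {
  tol <- tolerance_minutes * 60
  keep <- rep(TRUE, nrow(events))
  key <- paste(events$participant_id, events$medication)
  for (k in unique(key)) {
    idx <- which(key == k)
    dev <- idx[events$source[idx] == "device"]
    man <- idx[events$source[idx] == "manual"]
    if (!length(dev) || !length(man)) next
    dt <- as.numeric(events$timestamp[dev])
    mt <- as.numeric(events$timestamp[man])
    best <- list(card = -1L, cost = Inf, rm = integer(0))
    recurse <- function(i, used, cost, rm) {
      if (i > length(dev)) {
        card <- length(rm)
        if (card > best$card || (card == best$card && cost < best$cost)) {
          best <<- list(card = card, cost = cost, rm = rm)
        }
        return(invisible())
      }
      recurse(i + 1L, used, cost, rm)  # device i unmatched
      for (j in seq_along(man)) {
        if (!used[j] && abs(dt[i] - mt[j]) <= tol) {
          used[j] <- TRUE
          recurse(i + 1L, used, cost + abs(dt[i] - mt[j]), c(rm, man[j]))
          used[j] <- FALSE
        }
      }
    }
    recurse(1L, rep(FALSE, length(man)), 0, integer(0))
    keep[best$rm] <- FALSE
  }
  events[keep, , drop = FALSE]
}

# canonical multiset signature of an event table, for set comparison
event_signature <- function(events) {
  sort(paste(events$participant_id, as.numeric(events$timestamp),
             events$medication, events$source))
}

random_event_set <- function(n, tol_minutes = 60, n_participants = 1,
                             span_hours = 6) {
  base <- as.POSIXct("2015-08-03 06:00:00", tz = "UTC")
  tibble::tibble(
    participant_id = sample(sprintf("P%d", seq_len(n_participants)), n, TRUE),
    timestamp = base + round(runif(n, 0, span_hours * 3600)),
    medication = sample(c("controller", "rescue"), n, TRUE, prob = c(0.8, 0.2)),
    source = sample(c("device", "manual"), n, TRUE)
  ) |>
    dplyr::arrange(participant_id, timestamp)
}

# --- episode oracle: run-based direct reading of the definition --------------
# `flags`: integer vector indexed by study day, 0 = no report, 1 = report
# without symptoms, 2 = symptom report. Maximal runs of symptom reports
# (over observed report days) are episodes when the run's first day is at
# least `min_day` post-enrollment and at least one non-symptom report
# precedes the run; the enrollment-contiguous run starting before
# `min_day` (with no earlier report) is the initial exacerbation.
oracle_episodes <- function(flags, min_day = 7L) {
  obs <- unname(which(flags > 0L) - 1L)    # 0-based study days with a report
  sym <- unname(flags[flags > 0L] == 2L)
  starts <- integer(0)
  init_end <- NA_integer_
  if (length(obs)) {
    r <- rle(sym)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    sym_runs <- which(r$values)
    for (k in sym_runs) {
      first_day <- obs[run_start[k]]
      if (k == 1L) {                       # no report of any kind before
        if (first_day < min_day) init_end <- obs[run_end[k]]
        # else: indeterminate onset, neither exacerbation nor episode
      } else if (first_day >= min_day) {
        starts <- c(starts, first_day)
      }
    }
  }
  list(initial_exacerbation_end = init_end, episode_start_days = starts,
       episode_count = length(starts))
}

# --- naive adherence recount -------------------------------------------------
# Base-R loop recount of window counts, capped window and daily adherence,
# and the cohort mean, straight from the definitions.
oracle_recount <- function(events, regimen) {
  total <- 0; nday <- 0L
  for (r in seq_len(nrow(regimen))) {
    pid <- regimen$participant_id[r]
    days <- seq(regimen$enrollment_date[r], regimen$end_date[r], by = "day")
    for (d in days) {
      d <- as.Date(d, origin = "1970-01-01")
      am <- 0L; pm <- 0L
      for (e in seq_len(nrow(events))) {
        if (events$participant_id[e] != pid) next
        if (events$medication[e] != "controller") next
        if (as.Date(events$timestamp[e], tz = "UTC") != d) next
        hr <- as.integer(format(events$timestamp[e], "%H", tz = "UTC"))
        if (hr < 12) am <- am + 1L else pm <- pm + 1L
      }
      vals <- c()
      if (regimen$am_doses[r] > 0) {
        vals <- c(vals, min(am, regimen$am_doses[r]) / regimen$am_doses[r])
      }
      if (regimen$pm_doses[r] > 0) {
        vals <- c(vals, min(pm, regimen$pm_doses[r]) / regimen$pm_doses[r])
      }
      if (length(vals)) {
        total <- total + mean(vals)
        nday <- nday + 1L
      }
    }
  }
  if (nday == 0L) NA_real_ else total / nday
}

# random small cohort input for the recount checks
random_recount_instance <- function(max_events = 12) {
  n_part <- sample(1:2, 1)
  regimen <- tibble::tibble(
    participant_id = sprintf("P%d", seq_len(n_part)),
    enrollment_date = as.Date("2015-08-01"),
    end_date = as.Date("2015-08-01") + sample(1:4, n_part, TRUE),
    am_doses = sample(0:2, n_part, TRUE),
    pm_doses = sample(0:2, n_part, TRUE)
  )
  # ensure at least one prescribed dose somewhere
  if (all(regimen$am_doses + regimen$pm_doses == 0)) regimen$am_doses[1] <- 1L
  n <- sample(0:max_events, 1)
  events <- tibble::tibble(
    participant_id = sample(regimen$participant_id, n, TRUE),
    timestamp = as.POSIXct("2015-07-31 00:00:00", tz = "UTC") +
      round(runif(n, 0, 8 * 86400)),
    medication = sample(c("controller", "rescue"), n, TRUE, prob = c(0.85, 0.15)),
    source = "device"
  ) |>
    dplyr::arrange(participant_id, timestamp)
  list(events = events, regimen = regimen)
}

# small fully-specified daily table for acquisition/model tests
make_daily <- function(...) {
  rows <- tibble::tibble(...)
  defaults <- list(am_taken = 0L, pm_taken = 0L, am_adherence = NA_real_,
                   pm_adherence = NA_real_, daily_adherence = NA_real_,
                   has_ema = FALSE, has_any_data = FALSE, symptom_day = NA)
  for (nm in names(defaults)) {
    if (!nm %in% names(rows)) rows[[nm]] <- defaults[[nm]]
  }
  for (item in c("cough", "wheeze", "chest_tight", "stressed", "angry",
                 "bored", "happy", "relaxed")) {
    if (!item %in% names(rows)) rows[[item]] <- NA_integer_
  }
  if (!"date" %in% names(rows)) {
    rows$date <- as.Date("2015-08-01") + rows$study_day
  }
  rows
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
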