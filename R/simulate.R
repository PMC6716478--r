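# Synthetic longitudinal cohort generator.
#
# Emulates the structure of a two-month smartphone asthma-monitoring study:
# a small cohort on twice-daily controller regimens, low mean adherence
# with between-participant heterogeneity (logit-scale random effect,
# intercept calibrated so the *marginal* per-dose take probability equals
# the configured baseline), episodic symptom runs, daily latent mood
# levels, EMA reporting on a minority of days with optionally
# adherence-linked (informative) missingness, and device/manual event
# artifacts including jittered duplicate manual entries. Every latent
# quantity is returned in `truth` so each pipeline stage can be validated
# against known ground truth.

# Solve E[plogis(a + sd * Z)] = p for a (Gauss-Legendre via integrate).
calibrate_logit_mean <- function(p, sd) {
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  if (sd == 0) return(qlogis(p))
  marg <- function(a) {
    integrate(function(z) plogis(a + sd * z) * stats::dnorm(z),
              -8, 8, rel.tol = 1e-10)$value - p
  }
  uniroot(marg, c(qlogis(p) - 4 * sd, qlogis(p) + 4 * sd), tol = 1e-9)$root
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. Defaults emulate the monitored
#' study conditions: 14 participants followed for 60 days on a 1+1
#' twice-daily controller regimen, a marginal per-dose take probability of
#' 0.30 with logit-scale between-participant heterogeneity, EMA reports on
#' 20% of days, geometric symptom episodes, and occasional duplicate
#' manual entries around device actuations.
#'
#' @param n_participants Number of participants (default 14).
#' @param study_days Follow-up length in days including enrollment day
#'   (default 60).
#' @param am_doses,pm_doses Prescribed controller doses per window
#'   (default 1 and 1).
#' @param base_take_prob Marginal per-dose take probability (default 0.30).
#' @param take_logit_sd SD of the participant random effect on the logit
#'   of the take probability (default 0.8).
#' @param item_effects Named list mapping an EMA item to a numeric vector
#'   of additive take-probability shifts indexed by Likert level, e.g.
#'   `list(bored = c("3" = 0.20))`: on days where the latent level matches,
#'   the shift is added to the per-dose probability (then clamped to
#'   `[0, 1]`). Default: no planted effects.
#' @param episode_hazard Per-day probability of a new symptom episode
#'   starting outside an ongoing run (default 0.012).
#' @param episode_duration_mean Mean episode length in days, geometric
#'   (default 3).
#' @param init_exac_prob Probability a participant enrolls mid-exacerbation
#'   (default 0.5).
#' @param init_exac_duration_mean Mean initial-exacerbation length, days
#'   (default 3).
#' @param ema_report_prob Per-day EMA reporting probability (default 0.20).
#' @param missingness_coef Informative-missingness coefficient: the logit
#'   of the reporting probability is shifted by `coef * (p_day -
#'   base_take_prob)` where `p_day` is that day's latent take probability.
#'   Positive values make low-adherence days less likely to be reported.
#'   Default 0 (reporting missing completely at random).
#' @param device_failure_prob Probability a taken dose is captured only by
#'   a manual entry (default 0.05).
#' @param manual_entry_prob Probability a device-recorded dose also gets a
#'   duplicate manual entry (default 0.15).
#' @param duplicate_jitter_sd SD in minutes of the duplicate manual
#'   entry's timestamp around the device event (default 5).
#' @param rescue_rate Per-day probability of a rescue actuation
#'   (default 0.1).
#' @param enrollment_start First possible enrollment date.
#' @param enrollment_stagger_days Enrollments are drawn uniformly over this
#'   many days after `enrollment_start` (default 90).
#' @param mood_probs Named list of length-4 level probabilities for the
#'   mood items (`stressed`, `angry`, `bored`, `happy`, `relaxed`).
#' @param seed Integer RNG seed; fixes the generated cohort byte-for-byte.
#' @return List of class `"adhema_sim_config"`.
#' @export
simulation_config <- function(n_participants = 14,
                              study_days = 60,
                              am_doses = 1, pm_doses = 1,
                              base_take_prob = 0.30,
                              take_logit_sd = 0.8,
                              item_effects = list(),
                              episode_hazard = 0.012,
                              episode_duration_mean = 3,
                              init_exac_prob = 0.5,
                              init_exac_duration_mean = 3,
                              ema_report_prob = 0.20,
                              missingness_coef = 0,
                              device_failure_prob = 0.05,
                              manual_entry_prob = 0.15,
                              duplicate_jitter_sd = 5,
                              rescue_rate = 0.1,
                              enrollment_start = as.Date("2015-08-01"),
                              enrollment_stagger_days = 90,
                              mood_probs = NULL,
                              seed = 1L) {
  probs <- c(base_take_prob, ema_report_prob, device_failure_prob,
             manual_entry_prob, rescue_rate, episode_hazard, init_exac_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("All probability parameters must lie in [0, 1].",
          class = "adhema_config_error")
  }
  if (episode_duration_mean < 1 || init_exac_duration_mean < 1) {
    abort("Episode durations must average at least 1 day.",
          class = "adhema_config_error")
  }
  default_moods <- list(
    stressed = c(0.89, 0.08, 0.02, 0.01),
    angry    = c(0.90, 0.07, 0.02, 0.01),
    bored    = c(0.48, 0.30, 0.12, 0.10),
    happy    = c(0.10, 0.15, 0.25, 0.50),
    relaxed  = c(0.12, 0.18, 0.25, 0.45)
  )
  mood_probs <- utils::modifyList(default_moods, mood_probs %||% list())
  structure(
    list(n_participants = as.integer(n_participants),
         study_days = as.integer(study_days),
         am_doses = as.integer(am_doses), pm_doses = as.integer(pm_doses),
         base_take_prob = base_take_prob, take_logit_sd = take_logit_sd,
         item_effects = item_effects,
         episode_hazard = episode_hazard,
         episode_duration_mean = episode_duration_mean,
         init_exac_prob = init_exac_prob,
         init_exac_duration_mean = init_exac_duration_mean,
         ema_report_prob = ema_report_prob,
         missingness_coef = missingness_coef,
         device_failure_prob = device_failure_prob,
         manual_entry_prob = manual_entry_prob,
         duplicate_jitter_sd = duplicate_jitter_sd,
         rescue_rate = rescue_rate,
         enrollment_start = enrollment_start,
         enrollment_stagger_days = as.integer(enrollment_stagger_days),
         mood_probs = mood_probs,
         seed = as.integer(seed)),
    class = "adhema_sim_config"
  )
}

geom_duration <- function(n, mean_days) rgeom(n, 1 / mean_days) + 1L

# Symptom calendar for one participant: logical vector over study days.
simulate_symptom_calendar <- function(cfg) {
  nd <- cfg$study_days
  sym <- logical(nd)
  d <- 1L
  if (runif(1) < cfg$init_exac_prob) {
    len <- min(geom_duration(1L, cfg$init_exac_duration_mean), nd)
    sym[seq_len(len)] <- TRUE
    d <- len + 1L
  }
  while (d <= nd) {
    if (runif(1) < cfg$episode_hazard) {
      len <- geom_duration(1L, cfg$episode_duration_mean)
      end <- min(d + len - 1L, nd)
      sym[d:end] <- TRUE
      d <- end + 2L  # guarantee >= 1 clear day between generated runs
    } else {
      d <- d + 1L
    }
  }
  sym
}

sample_level <- function(n, probs) sample(0:3, n, replace = TRUE, prob = probs)

# Latent daily Likert levels for all 8 items given the symptom calendar.
simulate_item_levels <- function(sym, cfg) {
  nd <- length(sym)
  lv <- matrix(0L, nrow = nd, ncol = length(EMA_ITEMS),
               dimnames = list(NULL, EMA_ITEMS))
  ns <- sum(sym)
  if (ns) {
    # cough drives most symptom days, mostly "A little"; wheeze and chest
    # tightness are sparser and never beyond "A little"
    lv[sym, "cough"] <- sample(1:2, ns, replace = TRUE, prob = c(0.85, 0.15))
    lv[sym, "wheeze"] <- rbinom(ns, 1L, 0.2)
    lv[sym, "chest_tight"] <- rbinom(ns, 1L, 0.2)
  }
  for (item in names(cfg$mood_probs)) {
    lv[, item] <- sample_level(nd, cfg$mood_probs[[item]])
  }
  lv
}

item_shift <- function(levels_row, item_effects) {
  shift <- 0
  for (item in names(item_effects)) {
    eff <- item_effects[[item]]
    lv <- as.character(levels_row[[item]])
    if (lv %in% names(eff)) shift <- shift + eff[[lv]]
  }
  shift
}

#' Generate a synthetic monitoring cohort with known ground truth
#'
#' Draws a full cohort — actuation events (device and manual, including
#' jittered duplicate manual entries and rescue use), EMA reports, and the
#' regimen table — from [simulation_config()], together with a `truth`
#' component recording every latent quantity: per-participant random
#' effects, per-day take probabilities and symptom status, the true
#' episode calendar, and the episode starts expected to be detectable from
#' the realized reporting pattern.
#'
#' @param config A [simulation_config()].
#' @return List of class `"adhema_cohort"` with elements `events`, `ema`,
#'   `regimen` (tibbles as produced by the readers) and `truth` (list).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  alpha <- calibrate_logit_mean(cfg$base_take_prob, cfg$take_logit_sd)

  ids <- sprintf("P%03d", seq_len(cfg$n_participants))
  enrol <- cfg$enrollment_start +
    sample.int(cfg$enrollment_stagger_days + 1L, cfg$n_participants,
               replace = TRUE) - 1L
  b <- rnorm(cfg$n_participants, 0, cfg$take_logit_sd)
  regimen <- tibble::tibble(
    participant_id = ids,
    enrollment_date = enrol,
    end_date = enrol + cfg$study_days - 1L,
    am_doses = cfg$am_doses, pm_doses = cfg$pm_doses
  )

  events <- list(); emas <- list(); truth_daily <- list(); truth_eps <- list()

  for (i in seq_len(cfg$n_participants)) {
    nd <- cfg$study_days
    dates <- enrol[i] + 0:(nd - 1L)
    sym <- simulate_symptom_calendar(cfg)
    lv <- simulate_item_levels(sym, cfg)
    p_base_i <- if (is.finite(alpha)) plogis(alpha + b[i]) else plogis(alpha)

    shifts <- vapply(seq_len(nd), function(d) {
      item_shift(as.list(lv[d, ]), cfg$item_effects)
    }, numeric(1))
    p_day <- pmin(pmax(p_base_i + shifts, 0), 1)

    am_taken <- rbinom(nd, cfg$am_doses, p_day)
    pm_taken <- rbinom(nd, cfg$pm_doses, p_day)

    ev <- dose_events(ids[i], dates, am_taken, pm_taken, cfg)

    rescue_days <- which(rbinom(nd, 1L, cfg$rescue_rate) == 1L)
    if (length(rescue_days)) {
      ev <- dplyr::bind_rows(ev, tibble::tibble(
        participant_id = ids[i],
        timestamp = as.POSIXct(dates[rescue_days], tz = "UTC") +
          runif(length(rescue_days), 8, 22) * 3600,
        medication = "rescue", source = "device"))
    }

    rp <- plogis(qlogis(cfg$ema_report_prob) +
                   cfg$missingness_coef * (p_day - cfg$base_take_prob))
    if (cfg$missingness_coef == 0) rp <- rep(cfg$ema_report_prob, nd)
    reported <- runif(nd) < rp
    rep_days <- which(reported)
    if (length(rep_days)) {
      ema_i <- tibble::tibble(
        participant_id = ids[i],
        timestamp = as.POSIXct(dates[rep_days], tz = "UTC") +
          runif(length(rep_days), 12, 21) * 3600)
      for (item in EMA_ITEMS) ema_i[[item]] <- lv[rep_days, item]
      emas[[i]] <- ema_i
    }
    events[[i]] <- ev

    truth_daily[[i]] <- tibble::tibble(
      participant_id = ids[i], study_day = 0:(nd - 1L), date = dates,
      p_take = p_day, symptom = sym, am_taken = am_taken,
      pm_taken = pm_taken, reported = reported)
    truth_eps[[i]] <- episode_truth_one(ids[i], sym, reported,
                                        min_day = 7L)
  }

  events <- dplyr::bind_rows(events) |>
    dplyr::arrange(.data$participant_id, .data$timestamp)
  ema <- if (length(emas)) {
    dplyr::bind_rows(emas) |>
      dplyr::arrange(.data$participant_id, .data$timestamp)
  } else {
    tibble::as_tibble(c(
      list(participant_id = character(),
           timestamp = as.POSIXct(character(), tz = "UTC")),
      setNames(rep(list(integer()), length(EMA_ITEMS)), EMA_ITEMS)
    ))
  }

  structure(
    list(events = events, ema = ema, regimen = regimen,
         truth = list(
           participants = tibble::tibble(participant_id = ids,
                                         logit_re = b,
                                         p_base = plogis(alpha + b)),
           daily = dplyr::bind_rows(truth_daily),
           episodes = dplyr::bind_rows(truth_eps),
           alpha = alpha,
           config = unclass(cfg))),
    class = "adhema_cohort"
  )
}

# Timestamps for taken doses: AM doses 06:00-10:00, PM 18:00-22:00; a dose
# is device-recorded unless the device failed (manual-only); device doses
# may additionally spawn a jittered duplicate manual entry.
dose_events <- function(id, dates, am_taken, pm_taken, cfg) {
  rows <- list()
  emit <- function(day_dates, counts, lo, hi) {
    idx <- rep(seq_along(counts), counts)
    if (!length(idx)) return(NULL)
    base <- as.POSIXct(day_dates[idx], tz = "UTC") +
      runif(length(idx), lo, hi) * 3600
    dev_ok <- runif(length(idx)) >= cfg$device_failure_prob
    out <- tibble::tibble(
      participant_id = id, timestamp = base,
      medication = "controller",
      source = ifelse(dev_ok, "device", "manual"))
    dup <- dev_ok & runif(length(idx)) < cfg$manual_entry_prob
    if (any(dup)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        participant_id = id,
        timestamp = base[dup] + rnorm(sum(dup), 0, cfg$duplicate_jitter_sd * 60),
        medication = "controller", source = "manual"))
    }
    out
  }
  dplyr::bind_rows(emit(dates, am_taken, 6, 10), emit(dates, pm_taken, 18, 22))
}

# True and expected-detectable episodes for one participant, computed from
# the symptom calendar and the realized reporting pattern by the run-based
# definition (maximal symptom runs; a run is a detectable new episode when
# its first *observed* symptom day is >= min_day and an observed
# non-symptom report separates it from all earlier observed symptoms).
episode_truth_one <- function(id, sym, reported, min_day = 7L) {
  nd <- length(sym)
  runs <- rle(sym)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  true_runs <- which(runs$values)
  true_starts <- starts[true_runs] - 1L  # 0-based study days
  true_is_initial <- starts[true_runs] == 1L & true_starts < min_day
  n_true_episodes <- sum(!true_is_initial & true_starts >= 0)

  obs_days <- which(reported) - 1L
  obs_sym <- sym[reported]
  detectable <- detectable_runs(obs_days, obs_sym, min_day)

  tibble::tibble(
    participant_id = id,
    n_true_runs = length(true_runs),
    n_true_episodes = n_true_episodes,
    true_run_starts = list(true_starts),
    true_initial = list(true_is_initial),
    n_detectable = length(detectable),
    detectable_starts = list(detectable)
  )
}

# Run-based reading of the episode definition on an observed report
# sequence; intentionally distinct in structure from the day-by-day state
# machine in episode_scan(), as an internal cross-check.
detectable_runs <- function(obs_days, obs_sym, min_day = 7L) {
  if (!length(obs_days)) return(integer(0))
  r <- rle(obs_sym)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (k in which(r$values)) {
    first_day <- obs_days[starts[k]]
    has_prior_clear <- k > 1L  # an earlier (non-symptom) run of reports exists
    if (first_day >= min_day && has_prior_clear) out <- c(out, first_day)
  }
  out
}

#' Generate the per-participant symptom and episode ground-truth calendar
#'
#' Draws only the symptom-episode process and the EMA reporting pattern of
#' [simulate_cohort()] and returns the episode truth table: true symptom
#' runs, which of them are new episodes (versus the enrollment-contiguous
#' initial exacerbation), and the episode starts detectable from the
#' realized reporting pattern under the two-criterion rule. Useful for
#' studying the episode detector's censoring behaviour without the cost of
#' generating events.
#'
#' @param config A [simulation_config()].
#' @return Tibble with one row per participant: `n_true_runs`,
#'   `n_true_episodes`, `n_detectable`, plus list-columns
#'   `true_run_starts`, `true_initial`, `detectable_starts`.
#' @export
simulate_episode_truth <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  out <- lapply(seq_len(cfg$n_participants), function(i) {
    sym <- simulate_symptom_calendar(cfg)
    reported <- runif(cfg$study_days) < cfg$ema_report_prob
    episode_truth_one(sprintf("P%03d", i), sym, reported, min_day = 7L)
  })
  dplyr::bind_rows(out)
}

#' Write a simulated cohort to disk
#'
#' Emits `events.csv`, `ema.csv`, `regimen.csv` and `truth.json` into a
#' directory, in the formats the readers consume. Given the same
#' configuration (including seed), output files are byte-identical across
#' runs.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- cohort$events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(ev, file.path(dir, "events.csv"))
  em <- cohort$ema
  em$timestamp <- format(em$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(em, file.path(dir, "ema.csv"))
  readr::write_csv(cohort$regimen, file.path(dir, "regimen.csv"))
  truth <- cohort$truth
  truth$daily$date <- as.character(truth$daily$date)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
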