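# Readers and writers for the three study tables and the derived daily table.
#
# All timestamps are civil (wall-clock) local time: they are parsed into
# POSIXct with tz = "UTC" purely as a carrier, and no timezone arithmetic is
# ever applied. Dosing windows are defined by the clock on the wall.

#' Parse civil-time timestamps
#'
#' Accepts ISO-8601 date-times with either a `T` or a space separator, with
#' or without seconds, and bare dates (midnight assumed). Unparseable values
#' come back `NA`.
#'
#' @param x Character vector.
#' @return POSIXct vector (tz "UTC", used as a plain civil-time carrier).
#' @keywords internal
parse_civil_time <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out) & !is.na(x) & nzchar(x)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(x[todo], format = fmt, tz = "UTC")
  }
  out
}

civil_date <- function(ts) as.Date(ts, tz = "UTC")

civil_hour <- function(ts) as.integer(format(ts, "%H", tz = "UTC"))

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("File '%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "adhema_format_error")
  }
}

# Collects row-level problems and raises them all at once, with data line
# numbers (header = line 1, first data row = line 2).
raise_row_errors <- function(problems, path) {
  if (!length(problems)) return(invisible(NULL))
  abort(
    c(sprintf("Invalid rows in '%s':", path), stats::setNames(problems, rep("x", length(problems)))),
    class = "adhema_validation_error",
    problems = problems
  )
}

read_csv_quiet <- function(path, ...) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'", path), class = "adhema_format_error")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read inhaler actuation events
#'
#' Reads a CSV of timestamped inhaler actuations (one row per actuation) and
#' validates every row: timestamps must parse as ISO-8601, `medication` must
#' be `controller` or `rescue`, `source` must be `device` or `manual`. All
#' offending rows are reported together with their line numbers; nothing is
#' silently dropped.
#'
#' @param path Path to a CSV with columns
#'   `participant_id,timestamp,medication,source`.
#' @param config A [study_config()].
#' @return A tibble of events sorted by participant and timestamp, with
#'   columns `participant_id` (character), `timestamp` (civil-time POSIXct),
#'   `medication`, `source`.
#' @export
read_events <- function(path, config = study_config()) {
  raw <- read_csv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  require_columns(raw, c("participant_id", "timestamp", "medication", "source"), path)
  n <- nrow(raw)
  line <- seq_len(n) + 1L
  ts <- parse_civil_time(raw$timestamp)
  med <- tolower(trimws(raw$medication))
  src <- tolower(trimws(raw$source))

  problems <- character(0)
  bad_ts <- which(is.na(ts))
  bad_med <- which(!med %in% c("controller", "rescue"))
  bad_src <- which(!src %in% c("device", "manual"))
  if (length(bad_ts)) problems <- c(problems, sprintf(
    "line %d: unparseable timestamp '%s'", line[bad_ts], raw$timestamp[bad_ts]))
  if (length(bad_med)) problems <- c(problems, sprintf(
    "line %d: unknown medication '%s'", line[bad_med], raw$medication[bad_med]))
  if (length(bad_src)) problems <- c(problems, sprintf(
    "line %d: unknown source '%s'", line[bad_src], raw$source[bad_src]))
  raise_row_errors(problems, path)

  tibble::tibble(
    participant_id = as.character(raw$participant_id),
    timestamp = ts,
    medication = med,
    source = src
  ) |>
    dplyr::arrange(.data$participant_id, .data$timestamp)
}

likert_to_code <- function(x) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.integer(x))
  is_label <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(is_label)) {
    idx <- match(tolower(x[is_label]), tolower(LIKERT_LABELS))
    out[is_label] <- idx - 1L
  }
  out[!is.na(x) & !nzchar(x)] <- NA_integer_
  out
}

#' Read EMA self-reports
#'
#' Reads a CSV of ecological momentary assessment reports: one row per
#' report, with the eight 4-point Likert items (`cough`, `wheeze`,
#' `chest_tight`, `stressed`, `angry`, `bored`, `happy`, `relaxed`). Item
#' cells may hold integer codes 0-3, the text labels "Not at all" / "A
#' little" / "A lot" / "Extremely" (normalised to codes), or be blank
#' (missing item within an otherwise valid report).
#'
#' @inheritParams read_events
#' @return A tibble sorted by participant and timestamp with one integer
#'   column per item.
#' @export
read_ema <- function(path, config = study_config()) {
  raw <- read_csv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  require_columns(raw, c("participant_id", "timestamp", EMA_ITEMS), path)
  n <- nrow(raw)
  line <- seq_len(n) + 1L
  ts <- parse_civil_time(raw$timestamp)

  problems <- character(0)
  bad_ts <- which(is.na(ts))
  if (length(bad_ts)) problems <- c(problems, sprintf(
    "line %d: unparseable timestamp '%s'", line[bad_ts], raw$timestamp[bad_ts]))

  codes <- lapply(EMA_ITEMS, function(item) {
    raw_col <- raw[[item]]
    code <- likert_to_code(raw_col)
    bad <- which((is.na(code) & !is.na(raw_col) & nzchar(trimws(raw_col))) |
                   (!is.na(code) & !code %in% 0:3))
    if (length(bad)) problems <<- c(problems, sprintf(
      "line %d: %s value '%s' not a Likert level 0-3", line[bad], item, raw_col[bad]))
    code[!code %in% 0:3] <- NA_integer_
    code
  })
  names(codes) <- EMA_ITEMS
  raise_row_errors(problems, path)

  dplyr::bind_cols(
    tibble::tibble(participant_id = as.character(raw$participant_id), timestamp = ts),
    tibble::as_tibble(codes)
  ) |>
    dplyr::arrange(.data$participant_id, .data$timestamp)
}

#' Read the regimen / enrollment table
#'
#' One row per participant: enrollment date, study end date, and the number
#' of controller doses prescribed in the AM (00:00-11:59) and PM
#' (12:00-23:59) windows. Participants must carry at least one prescribed
#' controller dose per day, the study design having required an active
#' controller regimen.
#'
#' @param path Path to a CSV (or JSON array of records) with columns
#'   `participant_id,enrollment_date,end_date,am_doses,pm_doses`.
#' @return A tibble, one row per participant, dates as `Date`.
#' @export
read_regimen <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    raw <- read_csv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  }
  require_columns(raw, c("participant_id", "enrollment_date", "end_date",
                         "am_doses", "pm_doses"), path)
  n <- nrow(raw)
  line <- seq_len(n) + 1L
  enrol <- as.Date(parse_civil_time(raw$enrollment_date))
  end <- as.Date(parse_civil_time(raw$end_date))
  am <- suppressWarnings(as.integer(raw$am_doses))
  pm <- suppressWarnings(as.integer(raw$pm_doses))

  problems <- character(0)
  dup <- which(duplicated(raw$participant_id))
  if (length(dup)) problems <- c(problems, sprintf(
    "line %d: duplicate participant_id '%s'", line[dup], raw$participant_id[dup]))
  bad_date <- which(is.na(enrol) | is.na(end))
  if (length(bad_date)) problems <- c(problems, sprintf(
    "line %d: unparseable enrollment or end date", line[bad_date]))
  bad_order <- which(!is.na(enrol) & !is.na(end) & end < enrol)
  if (length(bad_order)) problems <- c(problems, sprintf(
    "line %d: end_date precedes enrollment_date", line[bad_order]))
  bad_dose <- which(is.na(am) | is.na(pm) | am < 0 | pm < 0)
  if (length(bad_dose)) problems <- c(problems, sprintf(
    "line %d: am_doses/pm_doses must be non-negative integers", line[bad_dose]))
  no_controller <- which(!is.na(am) & !is.na(pm) & am + pm < 1)
  if (length(no_controller)) problems <- c(problems, sprintf(
    "line %d: participant has no prescribed controller doses (am + pm must be >= 1)",
    line[no_controller]))
  raise_row_errors(problems, path)

  tibble::tibble(
    participant_id = as.character(raw$participant_id),
    enrollment_date = enrol,
    end_date = end,
    am_doses = am,
    pm_doses = pm
  )
}

#' Write / read the participant-day analysis table
#'
#' `write_daily_table()` serialises the daily records produced by
#' [build_daily_records()] to CSV; `read_daily_table()` restores them
#' field-for-field, so that `read(write(x))` equals `x`.
#'
#' @param records Daily-record tibble from [build_daily_records()].
#' @param path Output CSV path.
#' @return `write_daily_table()` returns `path` invisibly;
#'   `read_daily_table()` returns the tibble.
#' @export
write_daily_table <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' @rdname write_daily_table
#' @export
read_daily_table <- function(path) {
  spec <- readr::cols(
    participant_id = readr::col_character(),
    study_day = readr::col_integer(),
    date = readr::col_date(),
    am_taken = readr::col_integer(),
    pm_taken = readr::col_integer(),
    am_adherence = readr::col_double(),
    pm_adherence = readr::col_double(),
    daily_adherence = readr::col_double(),
    has_ema = readr::col_logical(),
    has_any_data = readr::col_logical(),
    symptom_day = readr::col_logical(),
    .default = readr::col_integer()
  )
  read_csv_quiet(path, col_types = spec)
}
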