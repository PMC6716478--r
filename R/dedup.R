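# Device/manual duplicate removal.
#
# Participants could log a medication use manually when the Bluetooth cap had
# not yet synced; once the cap transferred its record the same actuation
# exists twice. A manual entry is treated as a duplicate of a device event of
# the same medication when their timestamps agree to within the configured
# tolerance. Each device event cancels at most one manual entry; device
# events themselves are never removed. Among all feasible pairings we cancel
# as many manual entries as possible and, among those, the pairing with the
# smallest total timestamp discrepancy — for an isolated device event with
# one nearby manual entry this is exactly "cancel the nearest".

# Non-crossing DP over the two time-sorted point sets. For points on a line
# an optimal (max-cardinality, then min-total-gap) matching can always be
# uncrossed, so an O(nd * nm) dynamic programme suffices.
match_duplicates <- function(device_t, manual_t, tol_sec) {
  nd <- length(device_t)
  nm <- length(manual_t)
  if (nd == 0L || nm == 0L) return(integer(0))
  INF <- .Machine$double.xmax / 4
  # K[i, j], C[i, j]: best (pairs, cost) over device_t[i..nd] x manual_t[j..nm]
  K <- matrix(0L, nd + 1L, nm + 1L)
  C <- matrix(0, nd + 1L, nm + 1L)
  for (i in nd:1) {
    for (j in nm:1) {
      gap <- abs(device_t[i] - manual_t[j])
      bk <- K[i + 1L, j]; bc <- C[i + 1L, j]          # skip device i
      if (K[i, j + 1L] > bk || (K[i, j + 1L] == bk && C[i, j + 1L] < bc)) {
        bk <- K[i, j + 1L]; bc <- C[i, j + 1L]        # skip manual j
      }
      if (gap <= tol_sec) {
        mk <- K[i + 1L, j + 1L] + 1L
        mc <- C[i + 1L, j + 1L] + gap
        if (mk > bk || (mk == bk && mc < bc)) { bk <- mk; bc <- mc }
      }
      K[i, j] <- bk; C[i, j] <- bc
    }
  }
  # Backtrack, preferring a match whenever it attains the optimum.
  pairs <- integer(nd)  # manual index matched to each device, 0 = none
  i <- 1L; j <- 1L
  while (i <= nd && j <= nm) {
    gap <- abs(device_t[i] - manual_t[j])
    if (gap <= tol_sec &&
        K[i, j] == K[i + 1L, j + 1L] + 1L &&
        abs(C[i, j] - (C[i + 1L, j + 1L] + gap)) < 1e-9) {
      pairs[i] <- j; i <- i + 1L; j <- j + 1L
    } else if (K[i, j] == K[i, j + 1L] &&
               abs(C[i, j] - C[i, j + 1L]) < 1e-9) {
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  pairs
}

#' Remove manual entries duplicating device-recorded actuations
#'
#' Cancels, per participant and medication, manual log entries whose
#' timestamp lies within `tolerance_minutes` of an unmatched device event of
#' the same medication. Device events are never removed, each device event
#' cancels at most one manual entry, and among feasible pairings the one
#' cancelling the most manual entries (ties broken by smallest total time
#' discrepancy) is used. The removed entries, with their matched device
#' timestamps, are attached as the `"dedup_log"` attribute for audit.
#'
#' @param events Event tibble from [read_events()] (any participant mix;
#'   rows are grouped internally).
#' @param tolerance_minutes Positive matching tolerance in minutes.
#' @return The events tibble with duplicated manual rows removed, ordered by
#'   participant and timestamp; `attr(, "dedup_log")` holds one row per
#'   removed manual entry.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   participant_id = "P1",
#'   timestamp = as.POSIXct(c("2015-08-01 08:00", "2015-08-01 08:10"), tz = "UTC"),
#'   medication = "controller", source = c("device", "manual"))
#' deduplicate_events(ev, 60)
deduplicate_events <- function(events, tolerance_minutes = 60) {
  if (!is.numeric(tolerance_minutes) || length(tolerance_minutes) != 1 ||
      is.na(tolerance_minutes) || tolerance_minutes < 0) {
    abort("`tolerance_minutes` must be a single non-negative number.",
          class = "adhema_config_error")
  }
  tol_sec <- tolerance_minutes * 60
  events <- dplyr::arrange(events, .data$participant_id, .data$timestamp)
  drop <- logical(nrow(events))
  log_rows <- list()

  key <- paste(events$participant_id, events$medication, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    dev_idx <- idx[events$source[idx] == "device"]
    man_idx <- idx[events$source[idx] == "manual"]
    if (!length(dev_idx) || !length(man_idx)) next
    pairs <- match_duplicates(as.numeric(events$timestamp[dev_idx]),
                              as.numeric(events$timestamp[man_idx]),
                              tol_sec)
    matched <- which(pairs > 0L)
    if (length(matched)) {
      removed <- man_idx[pairs[matched]]
      drop[removed] <- TRUE
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        participant_id = events$participant_id[removed],
        medication = events$medication[removed],
        manual_timestamp = events$timestamp[removed],
        device_timestamp = events$timestamp[dev_idx[matched]],
        gap_minutes = abs(as.numeric(events$timestamp[removed]) -
                            as.numeric(events$timestamp[dev_idx[matched]])) / 60
      )
    }
  }

  out <- events[!drop, , drop = FALSE]
  attr(out, "dedup_log") <- if (length(log_rows)) {
    dplyr::bind_rows(log_rows)
  } else {
    tibble::tibble(participant_id = character(), medication = character(),
                   manual_timestamp = as.POSIXct(character(), tz = "UTC"),
                   device_timestamp = as.POSIXct(character(), tz = "UTC"),
                   gap_minutes = numeric())
  }
  out
}
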