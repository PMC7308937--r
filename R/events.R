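#' Create an empty annotation event log
#'
#' The engine tracks every annotator-facing action as a timestamped record:
#' which phase it belonged to (`validate`, `grow` or `name`), a free-form
#' action string, and how many objects it affected. Session splitting and
#' throughput statistics are computed from this log.
#'
#' @return A zero-row tibble with columns `timestamp` (POSIXct, UTC),
#'   `phase`, `action` (character) and `object_count` (integer).
#' @export
event_log <- function() {
  tibble::tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    phase = character(),
    action = character(),
    object_count = integer()
  )
}

#' Append an event to a log
#'
#' @param log Event log tibble (see [event_log()]).
#' @param phase One of `"validate"`, `"grow"`, `"name"`.
#' @param action Free-form action string (e.g. `"approve"`, `"judge_page"`).
#' @param object_count Number of objects the action affected.
#' @param timestamp Event time; defaults to the current time. Timestamps must
#'   be non-decreasing within a log.
#' @return The extended log.
#' @export
log_event <- function(log, phase, action, object_count,
                      timestamp = Sys.time()) {
  phase <- match.arg(phase, c("validate", "grow", "name"))
  if (nrow(log) > 0 && timestamp < max(log$timestamp)) {
    abort("event timestamps must be non-decreasing")
  }
  dplyr::bind_rows(log, tibble::tibble(
    timestamp = as.POSIXct(timestamp, tz = "UTC"),
    phase = phase,
    action = as.character(action),
    object_count = as.integer(object_count)
  ))
}

#' Read / write an event log as JSON lines
#'
#' One JSON object per line with fields `timestamp` (ISO-8601, UTC),
#' `phase`, `action`, `object_count`.
#'
#' @param path File path.
#' @return `read_event_log()`: the log tibble.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(event_log())
  recs <- purrr::map(lines, jsonlite::fromJSON)
  tibble::tibble(
    timestamp = as.POSIXct(vapply(recs, `[[`, "", "timestamp"),
                           format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"),
    phase = vapply(recs, `[[`, "", "phase"),
    action = vapply(recs, `[[`, "", "action"),
    object_count = vapply(recs, function(r) as.integer(r$object_count), integer(1))
  )
}

#' @rdname read_event_log
#' @param log Event log tibble.
#' @export
write_event_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(list(
      timestamp = format(log$timestamp[i], "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
      phase = log$phase[i],
      action = log$action[i],
      object_count = log$object_count[i]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Split an event log into work sessions
#'
#' Consecutive events separated by a gap *strictly greater* than `max_gap_min`
#' minutes start a new session, so breaks of exactly the maximum gap still
#' belong to one session. A session's duration is the time span between its
#' first and last event.
#'
#' @param log Event log tibble.
#' @param max_gap_min Maximum within-session gap, in minutes (default 10).
#' @return A tibble with one row per session: `session`, `start`, `end`,
#'   `duration_min`, `n_events`, `objects`. Empty log gives zero rows.
#' @export
split_sessions <- function(log, max_gap_min = 10) {
  if (nrow(log) == 0) {
    return(tibble::tibble(session = integer(), start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration_min = numeric(), n_events = integer(), objects = integer()))
  }
  log <- dplyr::arrange(log, .data$timestamp)
  gaps <- as.numeric(difftime(log$timestamp[-1], log$timestamp[-nrow(log)], units = "mins"))
  session <- cumsum(c(1L, as.integer(gaps > max_gap_min)))
  log$session <- session
  dplyr::summarise(
    dplyr::group_by(log, .data$session),
    start = min(.data$timestamp),
    end = max(.data$timestamp),
    duration_min = as.numeric(difftime(max(.data$timestamp), min(.data$timestamp), units = "mins")),
    n_events = dplyr::n(),
    objects = sum(.data$object_count),
    .groups = "drop"
  )
}
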