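#' Read a thigh-monitor events file
#'
#' The events file denotes the start and duration of each activity bout to
#' the nearest 0.1 s, with an integer activity code. Codes are translated to
#' the classes `sedentary`, `upright`, `other` via the dialect's code map;
#' unknown codes map to `"other"` with a warning.
#'
#' @param path path to the CSV events file.
#' @param dialect an [ap_dialect()] with column and code maps.
#' @return a data.frame of class `"activity_events"` with columns `start`
#'   (seconds since the recording's first midnight), `duration` (seconds) and
#'   `activity` (factor), time-ordered and non-overlapping. Bout intervals
#'   are half-open: `[start, start + duration)`.
#' @export
read_events <- function(path, dialect = ap_dialect()) {
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, showProgress = FALSE)
  cols <- dialect$events_cols
  missing_cols <- setdiff(unname(cols), names(dt))
  if (length(missing_cols) > 0)
    stop("dialect error: missing column(s) ", paste(missing_cols, collapse = ", "),
         " in ", path, call. = FALSE)
  start <- round(as.numeric(dt[[cols[["start"]]]]), 1)
  duration <- round(as.numeric(dt[[cols[["duration"]]]]), 1)
  code <- as.integer(dt[[cols[["code"]]]])
  if (any(!is.finite(start)) || any(!is.finite(duration)) || any(is.na(code)))
    stop("format error: non-numeric start/duration/code in ", path, call. = FALSE)
  if (any(duration <= 0))
    stop("format error: non-positive bout duration in ", path, call. = FALSE)
  if (is.unsorted(start, strictly = TRUE))
    stop("format error: events out of order in ", path, call. = FALSE)
  n <- length(start)
  # half-open intervals: an event may start exactly where the previous ends
  if (n > 1 && any(start[-1] < (start[-n] + duration[-n]) - 1e-9))
    stop("format error: overlapping events in ", path, call. = FALSE)
  code_map <- dialect$activity_codes
  activity <- rep("other", n)
  for (cls in names(code_map)) activity[code %in% code_map[[cls]]] <- cls
  unknown <- setdiff(unique(code), unlist(code_map))
  if (length(unknown) > 0)
    warning("unknown activity code(s) ", paste(unknown, collapse = ", "),
            " mapped to 'other'", call. = FALSE)
  out <- data.frame(start = start, duration = duration,
                    activity = factor(activity,
                                      levels = c("sedentary", "upright", "other")))
  class(out) <- c("activity_events", "data.frame")
  out
}

#' Write an events file
#'
#' Inverse of [read_events()]; start and duration are written at 0.1 s
#' resolution and classes are encoded with the dialect's code map (`other`
#' is written as code 99).
#'
#' @param events an `"activity_events"` data.frame.
#' @param path output CSV path.
#' @param dialect an [ap_dialect()].
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, dialect = ap_dialect()) {
  code_map <- dialect$activity_codes
  code <- vapply(as.character(events$activity), function(cls) {
    if (!is.null(code_map[[cls]])) as.integer(code_map[[cls]][1]) else 99L
  }, integer(1))
  dt <- data.table::data.table(start = sprintf("%.1f", events$start),
                               duration = sprintf("%.1f", events$duration),
                               code = code)
  cols <- dialect$events_cols
  data.table::setnames(dt, c(cols[["start"]], cols[["duration"]], cols[["code"]]))
  data.table::fwrite(dt, path, showProgress = FALSE)
  invisible(path)
}

parse_time_of_day <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (length(p) < 2 || length(p) > 3 || any(!is.finite(p)))
      return(NA_real_)
    sum(p * c(3600, 60, 1)[seq_along(p)])
  }, numeric(1))
}

format_time_of_day <- function(s) {
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, round(s %% 60))
}

#' Read a sleep diary
#'
#' One row per monitored day with self-reported wake-up and sleep times.
#' A sleep time at or before the wake time denotes sleep onset after
#' midnight (i.e., on the next calendar day); equal wake and sleep times are
#' rejected since the waking interval must have positive length.
#'
#' @param path path to a CSV with columns (per dialect) `date`,
#'   `wake`, `sleep`; times as `HH:MM` or `HH:MM:SS`.
#' @param dialect an [ap_dialect()].
#' @return a data.frame of class `"wear_diary"` with columns `date` (Date),
#'   `wake`, `sleep` (seconds of day) and `sleep_next_day` (logical).
#' @export
read_diary <- function(path, dialect = ap_dialect()) {
  if (!file.exists(path)) stop("diary file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          showProgress = FALSE)
  cols <- dialect$diary_cols
  missing_cols <- setdiff(unname(cols), names(dt))
  if (length(missing_cols) > 0)
    stop("dialect error: missing column(s) ", paste(missing_cols, collapse = ", "),
         " in ", path, call. = FALSE)
  date <- as.Date(dt[[cols[["date"]]]])
  if (any(is.na(date))) stop("format error: unparseable diary date in ", path, call. = FALSE)
  if (anyDuplicated(date))
    stop("format error: duplicate diary date ", format(date[duplicated(date)][1]),
         call. = FALSE)
  wake <- parse_time_of_day(dt[[cols[["wake"]]]])
  sleep <- parse_time_of_day(dt[[cols[["sleep"]]]])
  if (any(is.na(wake)) || any(is.na(sleep)))
    stop("format error: unparseable wake/sleep time in ", path, call. = FALSE)
  if (any(wake == sleep))
    stop("format error: wake time equals sleep time (waking interval empty)",
         call. = FALSE)
  out <- data.frame(date = date, wake = wake, sleep = sleep,
                    sleep_next_day = sleep < wake)
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("wear_diary", "data.frame")
  out
}

#' Write a sleep diary
#'
#' @param diary a `"wear_diary"` data.frame (see [read_diary()]).
#' @param path output CSV path.
#' @param dialect an [ap_dialect()].
#' @return `path`, invisibly.
#' @export
write_diary <- function(diary, path, dialect = ap_dialect()) {
  dt <- data.table::data.table(date = format(diary$date),
                               wake = format_time_of_day(diary$wake),
                               sleep = format_time_of_day(diary$sleep))
  cols <- dialect$diary_cols
  data.table::setnames(dt, c(cols[["date"]], cols[["wake"]], cols[["sleep"]]))
  data.table::fwrite(dt, path, showProgress = FALSE)
  invisible(path)
}

#' Diary waking windows on the recording clock
#'
#' Converts diary rows to half-open waking intervals `[wake, sleep)` in
#' seconds since midnight of `start_date`. A sleep time crossing midnight
#' extends the window into the next calendar day; the window is attributed to
#' the diary row's date.
#'
#' @param diary a `"wear_diary"` data.frame.
#' @param start_date the recording's first midnight (a Date).
#' @return data.frame with columns `date`, `start`, `end` (seconds).
#' @export
waking_windows <- function(diary, start_date) {
  day0 <- as.numeric(diary$date - as.Date(start_date)) * 86400
  end <- day0 + diary$sleep + ifelse(diary$sleep_next_day, 86400, 0)
  data.frame(date = diary$date, start = day0 + diary$wake, end = end)
}
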