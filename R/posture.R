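#' Extract waking sedentary bouts
#'
#' Sedentary events from the thigh monitor are intersected with the diary's
#' waking windows: bouts falling entirely within self-reported sleep are
#' dropped, partially overlapping bouts are clipped (`clipped = TRUE`), and a
#' bout is `prolonged` when its *clipped* waking duration exceeds the
#' threshold (default 3600 s, i.e. > 1 h). All intervals are half-open.
#'
#' @param events an `"activity_events"` data.frame ([read_events()]).
#' @param diary a `"wear_diary"` data.frame ([read_diary()]).
#' @param start_date the recording's first midnight (Date); the clock origin
#'   the event times are measured from.
#' @param prolonged_s prolonged-bout threshold in seconds (default 3600);
#'   strict: a bout is prolonged iff duration > `prolonged_s`.
#' @param strict if `TRUE` (default), a calendar day touched by a sedentary
#'   event but absent from the diary is an error; if `FALSE`, such time is
#'   excluded with a warning.
#' @return a data.frame of class `"sedentary_bouts"` with columns `bout_id`,
#'   `start`, `end`, `duration` (seconds), `prolonged`, `clipped`,
#'   `event_id` (row of the source event) and `date` (diary date of the
#'   enclosing waking window).
#' @export
extract_bouts <- function(events, diary, start_date = NULL,
                          prolonged_s = 3600, strict = TRUE) {
  if (is.null(start_date)) start_date <- min(diary$date)
  win <- waking_windows(diary, start_date)
  sed <- events[events$activity == "sedentary", , drop = FALSE]
  if (nrow(sed) > 0) {
    ev_days <- unique(unlist(lapply(seq_len(nrow(sed)), function(k) {
      seq(floor(sed$start[k] / 86400),
          floor((sed$start[k] + sed$duration[k] - 0.05) / 86400))
    })))
    diary_days <- as.numeric(diary$date - as.Date(start_date))
    missing_days <- setdiff(ev_days, diary_days)
    if (length(missing_days) > 0) {
      msg <- paste0("sedentary events on day(s) ",
                    paste(format(as.Date(start_date) + missing_days), collapse = ", "),
                    " with no diary entry")
      if (strict) stop("missing-diary error: ", msg, call. = FALSE)
      warning(msg, "; that time is excluded", call. = FALSE)
    }
  }
  rows <- list()
  ev_idx <- which(events$activity == "sedentary")
  for (k in ev_idx) {
    s <- events$start[k]
    e <- s + events$duration[k]
    for (w in seq_len(nrow(win))) {
      lo <- max(s, win$start[w])
      hi <- min(e, win$end[w])
      if (hi > lo + 1e-9) {
        rows[[length(rows) + 1]] <- data.frame(
          start = lo, end = hi, duration = hi - lo,
          clipped = (hi - lo) < (e - s) - 1e-9,
          event_id = k, date = win$date[w])
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(bout_id = integer(0), start = numeric(0), end = numeric(0),
                      duration = numeric(0), prolonged = logical(0),
                      clipped = logical(0), event_id = integer(0),
                      date = as.Date(character(0)))
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$start), , drop = FALSE]
    out$bout_id <- seq_len(nrow(out))
    out$prolonged <- out$duration > prolonged_s
    out <- out[, c("bout_id", "start", "end", "duration", "prolonged",
                   "clipped", "event_id", "date")]
    rownames(out) <- NULL
  }
  class(out) <- c("sedentary_bouts", "data.frame")
  out
}

#' Classify a sample's posture from its hip and knee angle
#'
#' Hip flexion below the lying threshold (default 30 deg, torso and thigh
#' near-parallel) is lying; otherwise the sample is sitting, split by knee
#' flexion into bent-legged (knee >= 45 deg) and straight-legged (knee < 45).
#' Boundary convention: hip exactly at the threshold classifies as sitting,
#' knee exactly at the threshold as bent-legged.
#'
#' @param hip,knee angles in degrees, in [0, 180]; `NA` allowed (degenerate
#'   samples) and propagated.
#' @param hip_lying hip threshold in degrees (default 30).
#' @param knee_bent knee threshold in degrees (default 45).
#' @return factor with levels `lying`, `bent_sit`, `straight_sit`.
#' @export
classify_posture <- function(hip, knee, hip_lying = 30, knee_bent = 45) {
  out <- rep(NA_character_, length(hip))
  out[hip < hip_lying] <- "lying"
  out[hip >= hip_lying & knee >= knee_bent] <- "bent_sit"
  out[hip >= hip_lying & knee < knee_bent] <- "straight_sit"
  factor(out, levels = c("lying", "bent_sit", "straight_sit"))
}

#' The standard 15-degree angle bins
#'
#' Six lower-closed intervals [0,15), [15,30), [30,45), [45,60), [60,75) and
#' [75,180], labelled `<15`, `15-30`, `30-45`, `45-60`, `60-75`, `>75`.
#'
#' @return named list with `breaks` and `labels`.
#' @export
angle_bins <- function() {
  list(breaks = c(0, 15, 30, 45, 60, 75, 180.000001),
       labels = c("<15", "15-30", "30-45", "45-60", "60-75", ">75"))
}

bin_angle <- function(x) {
  ab <- angle_bins()
  cut(x, breaks = ab$breaks, labels = ab$labels, right = FALSE)
}

# internal: per-sample tally of `value` (a factor) into seconds by
# date x class x value, excluding degenerate samples
tally_dwell <- function(series, bouts, value, value_name) {
  fs <- attr(series, "sample_rate")
  if (is.null(fs)) stop("series lacks a sample_rate attribute", call. = FALSE)
  if (!all(series$bout_id %in% bouts$bout_id))
    stop("consistency error: sample outside all bouts", call. = FALSE)
  keep <- !series$degenerate
  m <- match(series$bout_id[keep], bouts$bout_id)
  bout_cls <- factor(ifelse(bouts$prolonged, "prolonged", "non_prolonged"),
                     levels = c("prolonged", "non_prolonged"))
  bout_day <- factor(format(bouts$date))
  cls <- bout_cls[m]
  day <- bout_day[m]
  tab <- table(date = day, class = cls, value = value[keep])
  df <- as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
  df$dwell_s <- df$n / fs
  df$n <- NULL
  df$date <- as.Date(df$date)
  names(df)[names(df) == "value"] <- value_name
  df
}

#' Dwell time per 15-degree angle bin
#'
#' Each non-degenerate sample inside a sedentary bout contributes one sample
#' period (1/sample_rate s) to the bin containing its angle, tallied per
#' joint, calendar day and bout-length class.
#'
#' @param series a `"joint_angles"` data.frame ([joint_angles()]).
#' @param bouts the `"sedentary_bouts"` the series was computed over.
#' @return data.frame with columns `joint` (`hip`/`knee`), `date`, `class`
#'   (`prolonged`/`non_prolonged`), `bin` and `dwell_s`.
#' @export
bin_dwell <- function(series, bouts) {
  out <- do.call(rbind, lapply(c("hip", "knee"), function(j) {
    df <- tally_dwell(series, bouts, bin_angle(series[[j]]), "bin")
    df$joint <- j
    df
  }))
  out[, c("joint", "date", "class", "bin", "dwell_s")]
}

#' Dwell time per posture class
#'
#' As [bin_dwell()], with [classify_posture()] applied per sample: seconds in
#' lying, bent-legged sitting and straight-legged sitting per calendar day
#' and bout-length class.
#'
#' @inheritParams bin_dwell
#' @param hip_lying,knee_bent posture thresholds in degrees.
#' @return data.frame with columns `date`, `class`, `posture`, `dwell_s`.
#' @export
posture_dwell <- function(series, bouts, hip_lying = 30, knee_bent = 45) {
  lab <- classify_posture(series$hip, series$knee, hip_lying, knee_bent)
  out <- tally_dwell(series, bouts, lab, "posture")
  out[, c("date", "class", "posture", "dwell_s")]
}

#' Per-day quality-control metrics
#'
#' @param series a `"joint_angles"` data.frame.
#' @param bouts the matching `"sedentary_bouts"`.
#' @return data.frame with per-day sample counts, the degenerate-sample
#'   fraction and the number of clipped bouts.
#' @export
qc_report <- function(series, bouts) {
  m <- match(series$bout_id, bouts$bout_id)
  day <- factor(format(bouts$date))[m]
  n <- as.data.frame(table(date = day), responseName = "samples",
                     stringsAsFactors = FALSE)
  dg <- tapply(series$degenerate, day, sum)
  n$degenerate <- as.integer(dg[n$date])
  n$degenerate_frac <- n$degenerate / n$samples
  cb <- tapply(bouts$clipped, format(bouts$date), sum)
  n$clipped_bouts <- as.integer(cb[n$date])
  n$clipped_bouts[is.na(n$clipped_bouts)] <- 0L
  n$date <- as.Date(n$date)
  n
}
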