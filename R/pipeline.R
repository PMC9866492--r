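#' Pipeline configuration
#'
#' All analysis thresholds in one place, defaulting to the standard thresholds:
#' hip 30 deg (lying vs sitting), knee 45 deg (bent vs straight), prolonged
#' bout > 3600 s, degenerate-vector floor 0.2 g, and the 0.18 Hz first-order
#' zero-lag Butterworth.
#'
#' @param hip_lying,knee_bent posture thresholds in degrees.
#' @param prolonged_s prolonged-bout threshold in seconds.
#' @param eps degenerate-vector magnitude floor in g.
#' @param filter a [filter_spec()].
#' @param calibrate subtract the upright mounting offset ([mounting_offsets()])
#'   before classification (default `FALSE`).
#' @param strict_diary error (rather than warn) on sedentary days missing
#'   from the diary.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(hip_lying = 30, knee_bent = 45, prolonged_s = 3600,
                       eps = 0.2, filter = filter_spec(), calibrate = FALSE,
                       strict_diary = TRUE) {
  stopifnot(hip_lying > 0, knee_bent > 0, prolonged_s > 0, eps > 0)
  structure(list(hip_lying = hip_lying, knee_bent = knee_bent,
                 prolonged_s = prolonged_s, eps = eps, filter = filter,
                 calibrate = calibrate, strict_diary = strict_diary),
            class = "run_config")
}

#' Run the full posture analysis
#'
#' The single-command analysis: read the three raw acceleration files, the
#' thigh events file and the sleep diary; align and low-pass filter the
#' traces; extract waking sedentary bouts; compute per-sample hip and knee
#' flexion angles by the dot-product method; and accumulate dwell time per
#' 15-degree bin and per posture, split by prolonged vs non-prolonged bouts
#' and aggregated to minutes per day. No further input is required.
#'
#' Inputs may be given as file paths (with `dialect`, `version`,
#' `sample_rate`, `start_date` describing the files) or as already-built
#' objects ([accel_trace()], `"activity_events"`, `"wear_diary"`).
#'
#' @param torso,thigh,shin paths to the raw acceleration CSVs, or
#'   [accel_trace()] objects.
#' @param events path to the events CSV, or an `"activity_events"` object.
#' @param diary path to the diary CSV, or a `"wear_diary"` object.
#' @param dialect an [ap_dialect()].
#' @param config a [run_config()].
#' @param version,sample_rate,start_date file-reading metadata (ignored for
#'   object inputs).
#' @param participant_id identifier for the summary.
#' @return an object of class `"posture_analysis"`: list with `bouts`,
#'   `angles`, `bin_dwell`, `posture_dwell`, `summary`, `qc`, `offsets` and
#'   `config`.
#' @export
analyze_recording <- function(torso, thigh, shin, events, diary,
                              dialect = ap_dialect(), config = run_config(),
                              version = c("AP3", "AP4"), sample_rate = 20,
                              start_date = as.Date("2023-01-02"),
                              participant_id = "P1") {
  version <- match.arg(version)
  load_trace <- function(x, site) {
    if (inherits(x, "accel_trace")) return(x)
    read_accel(x, site = site, version = version, dialect = dialect,
               sample_rate = sample_rate, start_date = start_date)
  }
  torso <- load_trace(torso, "torso")
  thigh <- load_trace(thigh, "thigh")
  shin <- load_trace(shin, "shin")
  if (!inherits(events, "activity_events")) events <- read_events(events, dialect)
  if (!inherits(diary, "wear_diary")) diary <- read_diary(diary, dialect)
  start_date <- thigh$start_date

  traces <- align_traces(torso, thigh, shin)
  traces <- lapply(traces, lowpass, spec = config$filter)
  bouts <- extract_bouts(events, diary, start_date = start_date,
                         prolonged_s = config$prolonged_s,
                         strict = config$strict_diary)
  offsets <- c(hip = 0, knee = 0)
  if (isTRUE(config$calibrate))
    offsets <- mounting_offsets(traces$torso, traces$thigh, traces$shin,
                                events, eps = config$eps)
  angles <- joint_angles(traces$torso, traces$thigh, traces$shin, bouts,
                         eps = config$eps,
                         hip_offset = offsets[["hip"]],
                         knee_offset = offsets[["knee"]])
  bins <- bin_dwell(angles, bouts)
  postures <- posture_dwell(angles, bouts, hip_lying = config$hip_lying,
                            knee_bent = config$knee_bent)
  summ <- daily_summary(postures, diary, participant_id = participant_id)
  structure(list(bouts = bouts, angles = angles, bin_dwell = bins,
                 posture_dwell = postures, summary = summ,
                 qc = qc_report(angles, bouts), offsets = offsets,
                 config = config, start_date = start_date),
            class = "posture_analysis")
}

#' @export
print.posture_analysis <- function(x, ...) {
  cat(sprintf("<posture_analysis> %d sedentary bout(s) (%d prolonged, %d clipped) over %d day(s)\n",
              nrow(x$bouts), sum(x$bouts$prolonged), sum(x$bouts$clipped),
              x$summary$valid_days))
  print(x$summary)
  invisible(x)
}

#' Bin dwell as a six-row report table (min/day)
#'
#' Reshapes [bin_dwell()] output for one joint into the conventional layout:
#' rows are the 15-degree bins, columns prolonged / non-prolonged / total
#' min/day averaged across the given days (days without dwell in a class
#' count as 0).
#'
#' @param bins output of [bin_dwell()].
#' @param joint `"hip"` or `"knee"`.
#' @param n_days number of valid days to average over.
#' @return data.frame with columns `bin`, `prolonged`, `non_prolonged`,
#'   `total` (min/day).
#' @export
bin_report <- function(bins, joint = c("knee", "hip"), n_days) {
  joint <- match.arg(joint)
  b <- bins[bins$joint == joint, , drop = FALSE]
  labs <- angle_bins()$labels
  out <- data.frame(bin = labs)
  for (cl in c("prolonged", "non_prolonged")) {
    v <- tapply(b$dwell_s[b$class == cl], factor(b$bin[b$class == cl], labs), sum)
    v[is.na(v)] <- 0
    out[[cl]] <- as.numeric(v) / 60 / n_days
  }
  out$total <- out$prolonged + out$non_prolonged
  out
}

#' Write the analysis output tables
#'
#' Writes `bin_table_hip.csv` and `bin_table_knee.csv` (bins x bout-length
#' class, min/day), `posture_summary.csv` (per-day minutes), `bouts.csv`
#' (bout-level table with start time of day) and `qc.csv`.
#'
#' @param x a `"posture_analysis"`.
#' @param dir output directory (created if missing).
#' @return character vector of the paths written, invisibly.
#' @export
write_analysis <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    data.table::fwrite(df, p, showProgress = FALSE)
    paths <<- c(paths, p)
  }
  n_days <- x$summary$valid_days
  for (j in c("hip", "knee"))
    wr(bin_report(x$bin_dwell, j, n_days), paste0("bin_table_", j, ".csv"))
  wr(x$summary$days, "posture_summary.csv")
  bouts <- x$bouts
  bouts$start_time_of_day <- format_time_of_day(bouts$start %% 86400)
  wr(bouts, "bouts.csv")
  wr(x$qc, "qc.csv")
  invisible(paths)
}

#' Simulate a recording to disk
#'
#' Thin wrapper over [make_scenario()] + [write_scenario()]: generates a
#' seeded scenario and writes the five input files plus
#' `scenario_truth.csv` (the ground-truth min/day summary).
#'
#' @param dir output directory.
#' @param seed integer seed (always logged in the truth file name row).
#' @param ... passed to [make_scenario()].
#' @param dialect an [ap_dialect()].
#' @return list with `scenario`, `paths`, `truth`.
#' @export
simulate_recording <- function(dir, seed = 1, ..., dialect = ap_dialect()) {
  scenario <- make_scenario(seed = seed, ...)
  paths <- write_scenario(scenario, dir, dialect)
  truth <- ground_truth(scenario)
  tr <- truth$summary$days
  tr$seed <- seed
  p <- file.path(dir, "scenario_truth.csv")
  data.table::fwrite(tr, p, showProgress = FALSE)
  paths$truth <- p
  list(scenario = scenario, paths = paths, truth = truth)
}
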