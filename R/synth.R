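# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

SED_STATES <- c("sleep_lying", "lying", "bent_sit", "straight_sit")

# per-state orientation defaults: uniform ranges the per-bout angles are drawn
# from, all at least 10 deg clear of the 30/45 deg posture thresholds and
# obeying the sedentary thigh-incline rule (<= 20 deg from horizontal)
state_angle_ranges <- function() {
  list(sleep_lying  = list(hip = c(3, 10),   knee = c(3, 10),   incline = c(0, 4)),
       lying        = list(hip = c(3, 15),   knee = c(3, 15),   incline = c(0, 5)),
       bent_sit     = list(hip = c(80, 100), knee = c(80, 100), incline = c(0, 12)),
       straight_sit = list(hip = c(75, 95),  knee = c(12, 30),  incline = c(0, 12)),
       upright      = list(hip = c(0, 5),    knee = c(0, 5),    incline = c(80, 90)))
}

draw_angles <- function(state) {
  r <- state_angle_ranges()[[state]]
  c(hip = stats::runif(1, r$hip[1], r$hip[2]),
    knee = stats::runif(1, r$knee[1], r$knee[2]),
    incline = stats::runif(1, r$incline[1], r$incline[2]))
}

# split `total` seconds into non-prolonged bout durations around `mean_s`,
# each strictly below the prolonged threshold
split_nonprolonged <- function(total, mean_s, prolonged_s) {
  hi <- min(prolonged_s - 300, prolonged_s * 0.9)
  if (total <= 0) return(numeric(0))
  if (total < 240) return(total)
  durs <- numeric(0)
  left <- total
  while (left > 0) {
    d <- round(min(max(stats::rnorm(1, mean_s, mean_s * 0.3), 120), hi))
    if (d >= left - 120) {
      if (left <= hi) {
        durs <- c(durs, left)
      } else {
        durs <- c(durs, round(left / 2), left - round(left / 2))
      }
      left <- 0
    } else {
      durs <- c(durs, d)
      left <- left - d
    }
  }
  durs
}

#' Generate a ground-truth posture scenario
#'
#' Builds a seeded, fully reproducible schedule of posture segments tiling
#' `days` whole days: a diary-consistent sleep block each night and, within
#' each waking window, sedentary bouts (lying, bent-legged sitting,
#' straight-legged sitting) separated by upright breaks. Per-state waking
#' targets are met exactly each day; the fraction of sedentary time placed in
#' prolonged (> 1 h) bouts approximates `prolonged_fraction` per state (a
#' state whose prolonged share cannot fill a single > 1 h bout gets only
#' non-prolonged bouts). Defaults mirror typical free-living behaviour in
#' young adults: 7 days, 16 h waking, 439/113/69 min/day of bent-legged,
#' straight-legged and lying sedentary time, one third of it prolonged, 8.8
#' min mean non-prolonged bout length.
#'
#' @param seed integer seed; the scenario is a pure function of its arguments.
#' @param days number of whole recording days.
#' @param state_mix named numeric, target waking min/day for `bent_sit`,
#'   `straight_sit`, `lying`.
#' @param prolonged_fraction target fraction of each state's sedentary time
#'   accumulated in prolonged bouts.
#' @param wake,sleep diary times (`"HH:MM"`), identical each day; `sleep`
#'   must fall after `wake`.
#' @param noise_sd isotropic Gaussian accelerometer noise, in g (default
#'   0.05).
#' @param jitter_sd slow within-segment angular wander, in degrees RMS
#'   (default 0: segment angles are exactly constant).
#' @param sample_rate rendering sample rate in Hz.
#' @param device_version `"AP3"` or `"AP4"` quantization for rendering.
#' @param start_date calendar date of the first midnight.
#' @param mean_bout_min mean non-prolonged bout duration in minutes.
#' @param min_break_s minimum upright break between sedentary bouts, seconds.
#' @param prolonged_s prolonged threshold in seconds (> 1 h).
#' @return an object of class `"posture_scenario"`: list with `segments`
#'   (state, start, duration, hip, knee, incline), `diary`, and the
#'   generation parameters.
#' @export
make_scenario <- function(seed, days = 7,
                          state_mix = c(bent_sit = 439, straight_sit = 113,
                                        lying = 69),
                          prolonged_fraction = 0.33,
                          wake = "07:00", sleep = "23:00",
                          noise_sd = 0.05, jitter_sd = 0,
                          sample_rate = 20,
                          device_version = c("AP3", "AP4"),
                          start_date = as.Date("2023-01-02"),
                          mean_bout_min = 8.8, min_break_s = 60,
                          prolonged_s = 3600) {
  device_version <- match.arg(device_version)
  stopifnot(days >= 1, all(state_mix >= 0),
            prolonged_fraction >= 0, prolonged_fraction <= 1)
  if (!all(c("bent_sit", "straight_sit", "lying") %in% names(state_mix)))
    stop("state_mix must name bent_sit, straight_sit and lying", call. = FALSE)
  wake_s <- parse_time_of_day(wake)
  sleep_s <- parse_time_of_day(sleep)
  if (is.na(wake_s) || is.na(sleep_s) || sleep_s <= wake_s)
    stop("configuration error: need wake < sleep within the same day", call. = FALSE)
  waking <- sleep_s - wake_s
  targets <- round(state_mix[c("lying", "bent_sit", "straight_sit")] * 60)
  if (sum(targets) >= waking)
    stop("configuration error: state_mix (", sum(targets) / 60,
         " min) does not fit the ", waking / 60, " min waking window",
         call. = FALSE)
  with_seed(seed, {
    seg_list <- list()
    add <- function(state, duration, ang = draw_angles(state)) {
      seg_list[[length(seg_list) + 1]] <<-
        data.frame(state = state, duration = duration,
                   hip = ang[["hip"]], knee = ang[["knee"]],
                   incline = ang[["incline"]])
    }
    for (d in seq_len(days) - 1) {
      if (d == 0) add("sleep_lying", wake_s)
      # build the day's sedentary bouts
      bouts <- list()
      for (st in c("lying", "bent_sit", "straight_sit")) {
        target <- targets[[st]]
        if (target == 0) next
        prol_time <- round(prolonged_fraction * target)
        if (prol_time > prolonged_s + 60) {
          n_prol <- max(1, ceiling(prol_time / (prolonged_s * 1.5)))
          while (n_prol > 1 && prol_time / n_prol <= prolonged_s + 60)
            n_prol <- n_prol - 1
          base <- prol_time %/% n_prol
          pd <- rep(base, n_prol)
          pd[1] <- pd[1] + prol_time - sum(pd)
        } else {
          prol_time <- 0
          pd <- numeric(0)
        }
        npd <- split_nonprolonged(target - prol_time, mean_bout_min * 60,
                                  prolonged_s)
        for (dur in c(pd, npd))
          bouts[[length(bouts) + 1]] <- list(state = st, duration = dur)
      }
      bouts <- bouts[sample.int(length(bouts))]
      n_b <- length(bouts)
      upright_total <- waking - sum(targets)
      extra <- upright_total - (n_b + 1) * min_break_s
      if (extra < 0)
        stop("configuration error: not enough upright time for ", n_b,
             " bouts with ", min_break_s, " s breaks", call. = FALSE)
      w <- stats::rexp(n_b + 1)
      gaps <- min_break_s + floor(extra * w / sum(w))
      gaps[n_b + 1] <- upright_total - sum(gaps[seq_len(n_b)])
      for (k in seq_len(n_b)) {
        add("upright", gaps[k])
        add(bouts[[k]]$state, bouts[[k]]$duration)
      }
      add("upright", gaps[n_b + 1])
      # night sleep: to next wake, or to the end of the recording
      night <- if (d < days - 1) (86400 - sleep_s) + wake_s else 86400 - sleep_s
      add("sleep_lying", night)
    }
    segments <- do.call(rbind, seg_list)
    segments$start <- cumsum(c(0, segments$duration))[seq_len(nrow(segments))]
    segments <- segments[, c("state", "start", "duration", "hip", "knee", "incline")]
    stopifnot(sum(segments$duration) == days * 86400)
    diary <- data.frame(date = as.Date(start_date) + seq_len(days) - 1,
                        wake = wake_s, sleep = sleep_s, sleep_next_day = FALSE)
    class(diary) <- c("wear_diary", "data.frame")
    structure(list(seed = seed, days = days, segments = segments, diary = diary,
                   state_mix = state_mix, prolonged_fraction = prolonged_fraction,
                   noise_sd = noise_sd, jitter_sd = jitter_sd,
                   sample_rate = sample_rate, device_version = device_version,
                   start_date = as.Date(start_date), prolonged_s = prolonged_s),
              class = "posture_scenario")
  })
}

#' @export
print.posture_scenario <- function(x, ...) {
  cat(sprintf("<posture_scenario> seed %d, %d day(s), %d segments, noise %g g, jitter %g deg\n",
              x$seed, x$days, nrow(x$segments), x$noise_sd, x$jitter_sd))
  tot <- tapply(x$segments$duration, x$segments$state, sum) / 60 / x$days
  print(round(tot, 1))
  invisible(x)
}

# segment orientation (degrees from vertical) of the three segments;
# planar (sagittal) model: all rotations about the medio-lateral axis
segment_verticals <- function(hip, knee, incline) {
  thigh <- 90 - incline
  list(torso = thigh - hip, thigh = thigh, shin = thigh - knee)
}

# local gravity reading of a segment at angle `beta` (deg) from vertical:
# unit vector in the monitor frame, x = long axis, z = perpendicular
gravity_reading <- function(beta) {
  b <- beta * pi / 180
  cbind(sin(b), 0, cos(b))
}

#' Render a scenario to the three monitor traces
#'
#' Per segment each monitor's signal is the unit gravity vector implied by
#' the segment orientations, plus isotropic Gaussian noise (`noise_sd`) and,
#' if `jitter_sd > 0`, a slow sinusoidal angular wander of RMS `jitter_sd`
#' degrees on the hip and knee angles. Signals are quantized through the
#' device count map, so writing and re-reading the files is bit-exact.
#'
#' @param scenario a [make_scenario()] object.
#' @return named list of three [accel_trace()]s (`torso`, `thigh`, `shin`).
#' @export
render_traces <- function(scenario) {
  fs <- scenario$sample_rate
  seg <- scenario$segments
  counts <- as.integer(round(seg$duration * fs))
  with_seed(scenario$seed + 1L, {
    hip <- rep(seg$hip, counts)
    knee <- rep(seg$knee, counts)
    incline <- rep(seg$incline, counts)
    n <- length(hip)
    if (scenario$jitter_sd > 0) {
      tt <- (seq_len(n) - 1) / fs
      for (nm in c("hip", "knee")) {
        period <- stats::runif(1, 45, 90)
        phase <- stats::runif(1, 0, 2 * pi)
        wander <- scenario$jitter_sd * sqrt(2) *
          sin(2 * pi * tt / period + phase)
        assign(nm, get(nm) + wander)
      }
      hip <- pmin(pmax(hip, 0), 180)
      knee <- pmin(pmax(knee, 0), 180)
    }
    v <- segment_verticals(hip, knee, incline)
    traces <- list()
    for (site in c("torso", "thigh", "shin")) {
      xyz <- gravity_reading(v[[site]])
      xyz <- xyz + matrix(stats::rnorm(3 * n, sd = scenario$noise_sd), ncol = 3)
      # snap to the device grid so rendered traces round-trip exactly
      xyz[] <- counts_to_g(g_to_counts(xyz, scenario$device_version),
                           scenario$device_version)
      traces[[site]] <- accel_trace(xyz, site = site, sample_rate = fs,
                                    start_date = scenario$start_date,
                                    device_version = scenario$device_version)
    }
    traces
  })
}

#' Events implied by a scenario
#'
#' One sedentary event per maximal run of sedentary-state segments (thigh
#' incline <= 20 deg from horizontal), one upright event per upright run;
#' starts at 0.1 s resolution.
#'
#' @param scenario a [make_scenario()] object.
#' @return an `"activity_events"` data.frame.
#' @export
scenario_events <- function(scenario) {
  seg <- scenario$segments
  sed <- seg$state %in% SED_STATES
  r <- rle(sed)
  ends <- cumsum(r$lengths)
  starts_idx <- ends - r$lengths + 1
  out <- data.frame(
    start = round(seg$start[starts_idx], 1),
    duration = round(seg$start[ends] + seg$duration[ends] - seg$start[starts_idx], 1),
    activity = factor(ifelse(r$values, "sedentary", "upright"),
                      levels = c("sedentary", "upright", "other")))
  class(out) <- c("activity_events", "data.frame")
  out
}

#' Write a scenario's input files to a directory
#'
#' Renders the three acceleration traces, the events file and the diary in
#' the given dialect: `accel_torso.csv`, `accel_thigh.csv`, `accel_shin.csv`,
#' `events.csv`, `diary.csv`.
#'
#' @param scenario a [make_scenario()] object.
#' @param dir output directory (created if missing).
#' @param dialect an [ap_dialect()].
#' @return named list of the five file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir, dialect = ap_dialect()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traces <- render_traces(scenario)
  paths <- list()
  for (site in names(traces)) {
    p <- file.path(dir, paste0("accel_", site, ".csv"))
    write_accel(traces[[site]], p, dialect)
    paths[[site]] <- p
  }
  paths$events <- file.path(dir, "events.csv")
  write_events(scenario_events(scenario), paths$events, dialect)
  paths$diary <- file.path(dir, "diary.csv")
  write_diary(scenario$diary, paths$diary, dialect)
  invisible(paths)
}

#' Analytic ground truth of a scenario
#'
#' Computes, exactly from the segment schedule with interval arithmetic and
#' no rendering, the per-day posture dwell, the 15-degree bin dwell and the
#' daily summary the pipeline should recover. Bout-length classes use the
#' same waking-window clipping rule as the pipeline: a maximal sedentary run,
#' clipped to the waking window, is prolonged when the clipped duration
#' exceeds `scenario$prolonged_s`. Within-segment angular jitter is ignored
#' (segment nominal angles are used).
#'
#' @param scenario a [make_scenario()] object.
#' @param hip_lying,knee_bent posture thresholds in degrees.
#' @return list with `summary` (a `"posture_summary"`), `posture_dwell` and
#'   `bin_dwell` data.frames shaped like the pipeline outputs, and `runs`
#'   (the clipped sedentary runs with prolonged flags).
#' @export
ground_truth <- function(scenario, hip_lying = 30, knee_bent = 45) {
  seg <- scenario$segments
  seg$end <- seg$start + seg$duration
  sed <- seg$state %in% SED_STATES
  r <- rle(sed)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  run_start <- seg$start[starts_i][r$values]
  run_end <- seg$end[ends_i][r$values]
  win <- waking_windows(scenario$diary, scenario$start_date)
  runs <- list()
  for (k in seq_along(run_start)) {
    for (w in seq_len(nrow(win))) {
      lo <- max(run_start[k], win$start[w])
      hi <- min(run_end[k], win$end[w])
      if (hi > lo) runs[[length(runs) + 1]] <-
          data.frame(start = lo, end = hi, date = win$date[w],
                     prolonged = (hi - lo) > scenario$prolonged_s)
    }
  }
  runs <- do.call(rbind, runs)
  posture <- as.character(classify_posture(seg$hip, seg$knee, hip_lying, knee_bent))
  hip_bin <- as.character(bin_angle(seg$hip))
  knee_bin <- as.character(bin_angle(seg$knee))
  pd <- list(); bd <- list()
  for (i in which(sed)) {
    for (k in seq_len(nrow(runs))) {
      lo <- max(seg$start[i], runs$start[k])
      hi <- min(seg$end[i], runs$end[k])
      if (hi <= lo) next
      cls <- if (runs$prolonged[k]) "prolonged" else "non_prolonged"
      pd[[length(pd) + 1]] <- data.frame(
        date = runs$date[k], class = cls, posture = posture[i], dwell_s = hi - lo)
      bd[[length(bd) + 1]] <- data.frame(
        joint = c("hip", "knee"), date = runs$date[k], class = cls,
        bin = c(hip_bin[i], knee_bin[i]), dwell_s = hi - lo)
    }
  }
  agg <- function(df, keys) stats::aggregate(df["dwell_s"], df[keys], sum)
  pd <- agg(do.call(rbind, pd), c("date", "class", "posture"))
  bd <- agg(do.call(rbind, bd), c("joint", "date", "class", "bin"))
  summ <- daily_summary(pd, scenario$diary,
                        participant_id = paste0("truth-seed", scenario$seed))
  list(summary = summ, posture_dwell = pd, bin_dwell = bd, runs = runs)
}

#' Synthetic participant-level cohort (no rendering)
#'
#' Draws per-participant mean min/day for the three postures from independent
#' normal distributions (truncated at 0) and packs them as
#' `"posture_summary"` objects, splitting each posture's total into prolonged
#' and non-prolonged by `prolonged_fraction`. Used for testing the group
#' statistics at cohort scale without rendering signals.
#'
#' @param n participants.
#' @param seed integer seed.
#' @param means named numeric: cohort mean total min/day per posture.
#' @param sd between-participant standard deviation, min/day.
#' @param prolonged_fraction share of each posture's time that is prolonged.
#' @return list of `n` `"posture_summary"` objects.
#' @export
synth_cohort <- function(n = 20, seed = 1,
                         means = c(lying = 69, bent_sit = 439, straight_sit = 113),
                         sd = 30, prolonged_fraction = 0.33) {
  postures <- c("lying", "bent_sit", "straight_sit")
  classes <- c("prolonged", "non_prolonged", "total")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      tot <- pmax(stats::rnorm(3, means[postures], sd), 0)
      m <- matrix(NA_real_, 3, 3, dimnames = list(postures, classes))
      m[, "total"] <- tot
      m[, "prolonged"] <- prolonged_fraction * tot
      m[, "non_prolonged"] <- tot - m[, "prolonged"]
      structure(list(participant_id = sprintf("S%02d", i),
                     days = NULL, means = m, valid_days = NA_integer_),
                class = "posture_summary")
    })
  })
}
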