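# Shared fixture builders. Everything is generated in code; no stored data.

# a hand-specified scenario: segments given as (state, duration, hip, knee,
# incline) rows tiling `days` whole days; diary wake/sleep in seconds of day
toy_scenario <- function(segments, days = 1, wake_s = 7 * 3600,
                         sleep_s = 23 * 3600, noise_sd = 0, jitter_sd = 0,
                         sample_rate = 20, device_version = "AP3",
                         start_date = as.Date("2023-01-02"), seed = 1) {
  stopifnot(sum(segments$duration) == days * 86400)
  segments$start <- cumsum(c(0, segments$duration))[seq_len(nrow(segments))]
  diary <- data.frame(date = start_date + seq_len(days) - 1,
                      wake = wake_s, sleep = sleep_s, sleep_next_day = FALSE)
  class(diary) <- c("wear_diary", "data.frame")
  structure(list(seed = seed, days = days,
                 segments = segments[, c("state", "start", "duration",
                                         "hip", "knee", "incline")],
                 diary = diary, noise_sd = noise_sd, jitter_sd = jitter_sd,
                 sample_rate = sample_rate, device_version = device_version,
                 start_date = start_date, prolonged_s = 3600),
            class = "posture_scenario")
}

seg_row <- function(state, duration, hip, knee, incline) {
  data.frame(state = state, duration = duration, hip = hip, knee = knee,
             incline = incline)
}

# one day: sleep / upright / a few fixed-angle sedentary bouts / upright / sleep
simple_day_scenario <- function(noise_sd = 0, seed = 1) {
  segs <- rbind(
    seg_row("sleep_lying", 7 * 3600, 5, 5, 0),
    seg_row("upright", 2 * 3600, 2, 2, 88),
    seg_row("bent_sit", 5000, 90, 90, 5),        # prolonged (> 1 h)
    seg_row("upright", 1800, 2, 2, 85),
    seg_row("straight_sit", 1200, 85, 20, 8),
    seg_row("upright", 1800, 2, 2, 85),
    seg_row("lying", 2400, 10, 10, 2),
    seg_row("upright", 3 * 3600, 2, 2, 88),
    seg_row("bent_sit", 1500, 88, 92, 10),
    seg_row("upright", 86400 - (7 * 3600 + 2 * 3600 + 5000 + 1800 + 1200 +
                                1800 + 2400 + 3 * 3600 + 1500 + 3600), 2, 2, 88),
    seg_row("sleep_lying", 3600, 5, 5, 0))
  toy_scenario(segs, noise_sd = noise_sd, seed = seed)
}

# a diary with one row; events built from (start, duration, class) triplets
make_events <- function(...) {
  rows <- list(...)
  out <- data.frame(start = vapply(rows, `[[`, 0, 1),
                    duration = vapply(rows, `[[`, 0, 2),
                    activity = factor(vapply(rows, `[[`, "", 3),
                                      levels = c("sedentary", "upright", "other")))
  class(out) <- c("activity_events", "data.frame")
  out
}

make_diary <- function(dates, wake = "07:00", sleep = "23:00") {
  w <- triposture:::parse_time_of_day(wake)
  s <- triposture:::parse_time_of_day(sleep)
  out <- data.frame(date = as.Date(dates), wake = w, sleep = s,
                    sleep_next_day = s < w)
  class(out) <- c("wear_diary", "data.frame")
  out
}

# joint-angle series built directly (bypassing traces) for tally tests
make_series <- function(time, hip, knee, bout_id, degenerate = FALSE, fs = 20) {
  out <- data.frame(time = time, hip = hip, knee = knee, bout_id = bout_id,
                    degenerate = rep_len(degenerate, length(time)))
  attr(out, "sample_rate") <- fs
  class(out) <- c("joint_angles", "data.frame")
  out
}

make_bouts <- function(start, end, prolonged, date = as.Date("2023-01-02"),
                       clipped = FALSE) {
  out <- data.frame(bout_id = seq_along(start), start = start, end = end,
                    duration = end - start, prolonged = prolonged,
                    clipped = rep_len(clipped, length(start)),
                    event_id = seq_along(start),
                    date = rep_len(as.Date(date), length(start)))
  class(out) <- c("sedentary_bouts", "data.frame")
  out
}

# unit sinusoid trace on the x axis, z carrying 1 g
sine_trace <- function(f, secs = 120, fs = 20) {
  t <- (0:(secs * fs - 1)) / fs
  accel_trace(cbind(sin(2 * pi * f * t), 0, 1), site = "thigh",
              sample_rate = fs)
}

# measured amplitude of frequency f in a signal, by sin/cos regression over
# the central section (avoids edge transients)
measured_amplitude <- function(x, f, fs, trim_s = 30) {
  t <- (seq_along(x) - 1) / fs
  mid <- t > trim_s & t < max(t) - trim_s
  X <- cbind(sin(2 * pi * f * t[mid]), cos(2 * pi * f * t[mid]))
  sqrt(sum(stats::coef(stats::lm(x[mid] ~ X - 1))^2))
}
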