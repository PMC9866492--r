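test_that("extract_bouts intersects sedentary events with waking windows", {
  dia <- make_diary("2023-01-02")           # wake 07:00, sleep 23:00
  h <- 3600
  ev <- make_events(
    list(8 * h, 30 * 60, "sedentary"),      # 30 min, fully waking
    list(10 * h, 90 * 60, "sedentary"),     # 90 min, fully waking -> prolonged
    list(20 * h, 30 * 60, "upright"),       # not sedentary: ignored
    list(22 * h + 10 * 60, 90 * 60, "sedentary"),  # last 40 min after sleep
    list(2 * h, 60 * 60, "sedentary"))      # fully within sleep: dropped
  ev <- ev[order(ev$start), ]
  b <- extract_bouts(ev, dia, as.Date("2023-01-02"))
  expect_equal(nrow(b), 3)
  expect_equal(b$duration, c(30 * 60, 90 * 60, 50 * 60))
  expect_equal(b$prolonged, c(FALSE, TRUE, FALSE))
  expect_equal(b$clipped, c(FALSE, FALSE, TRUE))
  expect_equal(b$start[3], 22 * h + 10 * 60)
  expect_equal(b$end[3], 23 * h)
  expect_equal(format(unique(b$date)), "2023-01-02")
})

test_that("days with events but no diary entry error, or warn in lenient mode", {
  dia <- make_diary("2023-01-02")
  ev <- make_events(list(8 * 3600, 1800, "sedentary"),
                    list(86400 + 8 * 3600, 1800, "sedentary"))  # next day
  expect_error(extract_bouts(ev, dia, as.Date("2023-01-02")), "missing-diary")
  expect_warning(b <- extract_bouts(ev, dia, as.Date("2023-01-02"),
                                    strict = FALSE), "excluded")
  expect_equal(nrow(b), 1)
})

test_that("posture classification thresholds and boundary conventions", {
  expect_equal(as.character(classify_posture(10, 10)), "lying")
  expect_equal(as.character(classify_posture(90, 90)), "bent_sit")
  expect_equal(as.character(classify_posture(90, 20)), "straight_sit")
  # equality conventions: hip at threshold -> sitting; knee at threshold -> bent
  expect_equal(as.character(classify_posture(30, 45)), "bent_sit")
  expect_equal(as.character(classify_posture(30, 44.999)), "straight_sit")
  expect_equal(as.character(classify_posture(29.999, 170)), "lying")
  expect_true(is.na(classify_posture(NA, 90)))
})

test_that("bin edges are lower-closed and cover [0, 180]", {
  b <- triposture:::bin_angle(c(0, 14.999, 15, 44.999, 45, 75, 180))
  expect_equal(as.character(b),
               c("<15", "<15", "15-30", "30-45", "45-60", ">75", ">75"))
})

test_that("dwell binning matches a brute-force per-sample tally", {
  fs <- 20
  # 10 min of samples all at knee 50 deg -> 600 s in [45,60)
  n <- 10 * 60 * fs
  ser <- make_series(time = (0:(n - 1)) / fs, hip = rep(90, n),
                     knee = rep(50, n), bout_id = 1L, fs = fs)
  bouts <- make_bouts(0, 600, prolonged = FALSE)
  bd <- bin_dwell(ser, bouts)
  knee45 <- bd[bd$joint == "knee" & bd$bin == "45-60", ]
  expect_equal(sum(knee45$dwell_s), 600)
  expect_equal(sum(bd$dwell_s[bd$joint == "knee"]), 600)
  expect_equal(sum(knee45$dwell_s[knee45$class == "non_prolonged"]), 600)
  expect_equal(sum(knee45$dwell_s[knee45$class == "prolonged"]), 0)
  # a sample at exactly 45 deg falls in [45,60)
  ser2 <- make_series(0, 45, 45, 1L, fs = fs)
  bd2 <- bin_dwell(ser2, bouts)
  expect_equal(sum(bd2$dwell_s[bd2$joint == "hip" & bd2$bin == "45-60"]), 1 / fs)
  expect_equal(sum(bd2$dwell_s[bd2$joint == "hip"]), 1 / fs)

  # mixed random series vs an exhaustive per-sample counting oracle
  set.seed(31)
  n <- 5000
  bouts <- make_bouts(start = c(0, 400), end = c(300, 650),
                      prolonged = c(FALSE, TRUE))
  in_b1 <- 0:(300 * fs - 1) / fs
  in_b2 <- 400 + 0:(250 * fs - 1) / fs
  tt <- c(in_b1, in_b2)
  ser <- make_series(time = tt, hip = runif(length(tt), 0, 180),
                     knee = runif(length(tt), 0, 180),
                     bout_id = rep(1:2, c(length(in_b1), length(in_b2))),
                     degenerate = runif(length(tt)) < 0.03, fs = fs)
  bd <- bin_dwell(ser, bouts)
  ab <- angle_bins()
  for (joint in c("hip", "knee")) {
    for (cls in c("prolonged", "non_prolonged")) {
      keep <- !ser$degenerate & (ser$bout_id == (if (cls == "prolonged") 2 else 1))
      counts <- table(cut(ser[[joint]][keep], ab$breaks, ab$labels, right = FALSE))
      got <- bd[bd$joint == joint & bd$class == cls, ]
      expect_equal(got$dwell_s[match(ab$labels, got$bin)],
                   as.numeric(counts) / fs,
                   label = paste("oracle tally", joint, cls))
    }
  }
})

test_that("posture dwell partitions total non-degenerate time exactly", {
  set.seed(37)
  fs <- 20
  n <- 8000
  bouts <- make_bouts(0, n / fs, prolonged = TRUE)
  ser <- make_series(time = (0:(n - 1)) / fs,
                     hip = runif(n, 0, 180), knee = runif(n, 0, 180),
                     bout_id = 1L, degenerate = runif(n) < 0.05, fs = fs)
  pd <- posture_dwell(ser, bouts)
  expect_equal(sum(pd$dwell_s), sum(!ser$degenerate) / fs)
  expect_equal(sort(unique(as.character(pd$posture))),
               sort(c("lying", "bent_sit", "straight_sit")))
  # oracle: direct classification count
  lab <- classify_posture(ser$hip, ser$knee)
  for (p in levels(lab))
    expect_equal(sum(pd$dwell_s[pd$posture == p]),
                 sum(lab == p & !ser$degenerate) / fs)
  # a sample claiming a nonexistent bout is a consistency error
  bad <- make_series(0, 90, 90, 99L, fs = fs)
  expect_error(posture_dwell(bad, bouts), "consistency error")
})

test_that("prolonged + non-prolonged dwell adds to total; threshold is monotone", {
  sc <- simple_day_scenario()
  ev <- scenario_events(sc)
  dia <- sc$diary
  tr <- lapply(render_traces(sc), lowpass)
  prolonged_dwell <- function(thr) {
    b <- extract_bouts(ev, dia, sc$start_date, prolonged_s = thr)
    ja <- joint_angles(tr$torso, tr$thigh, tr$shin, b)
    pd <- posture_dwell(ja, b)
    c(prolonged = sum(pd$dwell_s[pd$class == "prolonged"]),
      total = sum(pd$dwell_s))
  }
  thresholds <- c(1800, 3600, 5400)
  res <- vapply(thresholds, prolonged_dwell, numeric(2))
  # total is threshold-invariant; prolonged dwell never increases with the cut
  expect_equal(unname(res["total", ]), rep(unname(res["total", 1]), 3))
  expect_true(all(diff(res["prolonged", ]) <= 0))
})
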