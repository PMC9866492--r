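test_that("scenario generation is a pure function of its seed", {
  a <- make_scenario(seed = 5, days = 2)
  b <- make_scenario(seed = 5, days = 2)
  expect_identical(a$segments, b$segments)
  expect_identical(a$diary, b$diary)
  c <- make_scenario(seed = 6, days = 2)
  expect_false(identical(a$segments, c$segments))
  # generation does not disturb the caller's RNG stream
  set.seed(99); x1 <- rnorm(3)
  set.seed(99); invisible(make_scenario(seed = 5, days = 1)); x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("infeasible posture targets are a configuration error", {
  expect_error(make_scenario(seed = 1, state_mix = c(bent_sit = 900,
                                                     straight_sit = 400,
                                                     lying = 200)),
               "configuration error")
  expect_error(make_scenario(seed = 1, wake = "09:00", sleep = "08:00"),
               "configuration error")
})

test_that("segments tile the recording and realized totals hit the targets", {
  sc <- make_scenario(seed = 8, days = 3)
  seg <- sc$segments
  expect_equal(sum(seg$duration), 3 * 86400)
  expect_equal(seg$start, cumsum(c(0, seg$duration))[seq_len(nrow(seg))])
  tot <- tapply(seg$duration, seg$state, sum) / 60 / 3
  for (st in c("bent_sit", "straight_sit", "lying"))
    expect_equal(unname(tot[st]), unname(sc$state_mix[st]), tolerance = 1e-8)
})

test_that("scenario angles respect the posture and incline invariants", {
  sc <- make_scenario(seed = 12, days = 2)
  seg <- sc$segments
  sed <- seg$state %in% c("sleep_lying", "lying", "bent_sit", "straight_sit")
  expect_true(all(seg$incline[sed] <= 20))
  expect_true(all(seg$incline[!sed] > 20))
  expect_true(all(seg$hip[seg$state %in% c("lying", "sleep_lying")] < 30))
  expect_true(all(seg$knee[seg$state == "bent_sit"] >= 45))
  expect_true(all(seg$knee[seg$state == "straight_sit"] < 45))
  expect_true(all(seg$hip[seg$state == "straight_sit"] >= 30))
})

test_that("emitted events are exactly the maximal sedentary runs", {
  sc <- make_scenario(seed = 13, days = 1)
  ev <- scenario_events(sc)
  seg <- sc$segments
  sed <- seg$state %in% c("sleep_lying", "lying", "bent_sit", "straight_sit")
  # events alternate, tile the day, and agree with the <= 20 deg incline rule
  expect_equal(sum(ev$duration), 86400)
  expect_true(all(abs(diff(as.integer(ev$activity))) == 1))
  for (k in seq_len(nrow(ev))) {
    inside <- seg$start >= ev$start[k] - 1e-9 &
      seg$start < ev$start[k] + ev$duration[k] - 1e-9
    expect_true(all(sed[inside] == (ev$activity[k] == "sedentary")))
    expect_true(all((seg$incline[inside] <= 20) ==
                    (ev$activity[k] == "sedentary")))
  }
})

test_that("ground truth is the identity on a single-bout day", {
  segs <- rbind(
    seg_row("sleep_lying", 7 * 3600, 5, 5, 0),
    seg_row("upright", 3600, 2, 2, 88),
    seg_row("bent_sit", 1800, 90, 90, 5),
    seg_row("upright", 86400 - 7 * 3600 - 3600 - 1800 - 3600, 2, 2, 88),
    seg_row("sleep_lying", 3600, 5, 5, 0))
  sc <- toy_scenario(segs)
  gt <- ground_truth(sc)
  expect_equal(gt$summary$means["bent_sit", "total"], 30)
  expect_equal(gt$summary$means["bent_sit", "prolonged"], 0)
  expect_equal(sum(gt$summary$means[c("lying", "straight_sit"), "total"]), 0)
  # the sleep runs fall wholly outside the waking window; one run remains
  expect_equal(nrow(gt$runs), 1)
})

test_that("ground truth matches a brute-force tally of the noiseless rendering", {
  sc <- simple_day_scenario(noise_sd = 0)
  gt <- ground_truth(sc)
  tr <- lapply(render_traces(sc), lowpass)
  bouts <- extract_bouts(scenario_events(sc), sc$diary, sc$start_date)
  ja <- joint_angles(tr$torso, tr$thigh, tr$shin, bouts)
  pd <- posture_dwell(ja, bouts)
  s <- daily_summary(pd, sc$diary)
  # one sample period of slack per segment boundary; filter smears a few
  # seconds across boundaries, but all angles are far from the thresholds
  expect_equal(s$means, gt$summary$means, tolerance = 0.05)
  bd <- bin_dwell(ja, bouts)
  agg <- function(df) tapply(df$dwell_s, list(df$joint, df$bin, df$class), sum)
  got <- agg(bd); want <- agg(gt$bin_dwell)
  got[is.na(got)] <- 0
  want2 <- array(0, dim(got), dimnames(got))
  for (j in rownames(want)) for (b in colnames(want)) for (cl in dimnames(want)[[3]])
    if (!is.na(want[j, b, cl])) want2[j, b, cl] <- want[j, b, cl]
  # filter transients at posture changes can move a handful of seconds
  # between bins; everything else matches
  expect_lt(max(abs(got - want2)), 30)
  expect_equal(sum(got), sum(want2), tolerance = 1e-8)
})

test_that("prolonged share of sedentary time tracks the requested mix", {
  sc <- make_scenario(seed = 21, days = 2, prolonged_fraction = 0.33)
  gt <- ground_truth(sc)
  tot <- sum(gt$summary$means[, "total"])
  prol <- sum(gt$summary$means[, "prolonged"])
  # only states whose prolonged share can fill a > 1 h bout contribute;
  # with the default mix that is bent-legged sitting: 0.33 * 439 of 621 min
  expect_equal(prol / tot, 0.33 * 439 / 621, tolerance = 0.02)
})

test_that("rendered cohort statistics respect the requested shift", {
  sc <- synth_cohort(n = 10, seed = 31, means = c(lying = 50, bent_sit = 300,
                                                  straight_sit = 100), sd = 20)
  m <- cohort_matrix(sc)
  expect_equal(unname(colMeans(m)), c(50, 300, 100), tolerance = 0.35)
  expect_true(all(m >= 0))
})
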