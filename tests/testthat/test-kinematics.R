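test_that("vector_angle closed-form cases", {
  expect_equal(vector_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(vector_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(vector_angle(c(2, 0, 0), c(1, 1, 0)), 45)
  expect_equal(vector_angle(c(1, 0, 0), c(-1, 0, 0)), 180)
})

test_that("vector_angle matches an independent atan2 oracle on random pairs", {
  # oracle: angle from the cross-product / dot-product pair, a numerically
  # distinct route to the same geometric quantity
  oracle <- function(a, b) {
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    atan2(sqrt(sum(cr^2)), sum(a * b)) * 180 / pi
  }
  set.seed(101)
  for (i in 1:1000) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    b <- rnorm(3); b <- b / sqrt(sum(b^2))
    expect_lt(abs(vector_angle(a, b) - oracle(a, b)), 1e-9)
  }
})

test_that("vector_angle is symmetric, scale-invariant, and flags degeneracy", {
  set.seed(7)
  a <- matrix(rnorm(300), ncol = 3)
  b <- matrix(rnorm(300), ncol = 3)
  z <- 1e-12  # disable the magnitude floor: properties hold for any scaling
  expect_equal(vector_angle(a, b, eps = z), vector_angle(b, a, eps = z))
  expect_equal(vector_angle(a, b, eps = z),
               vector_angle(2.7 * a, 0.4 * b, eps = z))
  expect_equal(vector_angle(a, 3 * a, eps = z), rep(0, 100), tolerance = 1e-6)
  expect_equal(vector_angle(a, -a, eps = z), rep(180, 100), tolerance = 1e-6)
  expect_true(is.na(vector_angle(c(0.1, 0, 0), c(0, 0, 1))))
  expect_false(is.na(vector_angle(c(0.1, 0, 0), c(0, 0, 1), eps = 0.05)))
})

test_that("isotropic 0.05 g noise perturbs 1 g gravity angles predictably", {
  set.seed(23)
  n <- 20000
  # one perturbed vector against a clean reference: RMS ~ 0.05 rad = 2.9 deg
  a <- cbind(0, 0, 1)[rep(1, n), ] + matrix(rnorm(3 * n, 0, 0.05), ncol = 3)
  b0 <- cbind(1, 0, 0)[rep(1, n), ]
  expect_lt(sqrt(mean((vector_angle(a, b0) - 90)^2)), 3)
  # both perturbed: variances add, RMS ~ sqrt(2) * 0.05 rad = 4.05 deg
  b <- b0 + matrix(rnorm(3 * n, 0, 0.05), ncol = 3)
  rms2 <- sqrt(mean((vector_angle(a, b) - 90)^2))
  expect_equal(rms2, sqrt(2) * 0.05 * 180 / pi, tolerance = 0.05)
})

test_that("joint_angles reproduces static sitting and lying geometry", {
  n <- 1200
  const <- function(v, site) accel_trace(matrix(rep(v, each = n), ncol = 3), site)
  bouts <- make_bouts(start = 10, end = 50, prolonged = FALSE)
  # sitting: torso vertical, thigh horizontal, shin vertical
  ja <- joint_angles(const(c(0, 0, 1), "torso"), const(c(1, 0, 0), "thigh"),
                     const(c(0, 0, 1), "shin"), bouts)
  expect_equal(nrow(ja), 40 * 20)
  expect_equal(unique(ja$hip), 90)
  expect_equal(unique(ja$knee), 90)
  expect_equal(unique(ja$bout_id), 1)
  # lying: all three horizontal, same direction
  ja <- joint_angles(const(c(1, 0, 0), "torso"), const(c(1, 0, 0), "thigh"),
                     const(c(1, 0, 0), "shin"), bouts)
  expect_equal(unique(ja$hip), 0)
  expect_equal(unique(ja$knee), 0)
  # bout outside the trace span is a coverage error
  far <- make_bouts(start = 100, end = 200, prolonged = FALSE)
  expect_error(joint_angles(const(c(0, 0, 1), "torso"), const(c(1, 0, 0), "thigh"),
                            const(c(0, 0, 1), "shin"), far), "coverage error")
})

test_that("per-sample angles on a noiseless rendering match scenario ground truth", {
  sc <- simple_day_scenario(noise_sd = 0)
  tr <- lapply(render_traces(sc), lowpass)
  bouts <- extract_bouts(scenario_events(sc), sc$diary, sc$start_date)
  ja <- joint_angles(tr$torso, tr$thigh, tr$shin, bouts)
  seg <- sc$segments
  # ground-truth angle per sample from the segment schedule, away from
  # segment boundaries (the zero-lag filter smears a few seconds either side)
  idx <- findInterval(ja$time, seg$start)
  interior <- abs(ja$time - seg$start[idx]) > 5 &
    abs(ja$time - (seg$start[idx] + seg$duration[idx])) > 5
  expect_gt(mean(interior), 0.9)
  # 8-bit quantization tilts each unit gravity vector by up to
  # asin(sqrt(2)/126) ~ 0.64 deg, so a pair can differ by up to ~1.3 deg
  expect_lt(max(abs(ja$hip[interior] - seg$hip[idx][interior])), 1.3)
  expect_lt(max(abs(ja$knee[interior] - seg$knee[idx][interior])), 1.3)

  # the same geometry without quantization is exact to numerical precision
  verts <- triposture:::segment_verticals(seg$hip, seg$knee, seg$incline)
  hip_truth <- abs(verts$thigh - verts$torso)
  expect_equal(hip_truth, seg$hip, tolerance = 1e-9)
  knee_truth <- abs(verts$thigh - verts$shin)
  expect_equal(knee_truth, seg$knee, tolerance = 1e-9)
})

test_that("mounting offsets are recovered from upright time and floored at 0", {
  n <- 2400
  rot <- function(deg) c(sin(deg * pi / 180), 0, cos(deg * pi / 180))
  torso <- accel_trace(matrix(rep(rot(6), each = n), ncol = 3), "torso")
  thigh <- accel_trace(matrix(rep(rot(0), each = n), ncol = 3), "thigh")
  shin <- accel_trace(matrix(rep(rot(-4), each = n), ncol = 3), "shin")
  ev <- make_events(list(0, n / 20, "upright"))
  off <- mounting_offsets(torso, thigh, shin, ev)
  expect_equal(unname(off), c(6, 4), tolerance = 1e-6)
  bouts <- make_bouts(0, n / 20, FALSE)
  ja <- joint_angles(torso, thigh, shin, bouts,
                     hip_offset = off[["hip"]], knee_offset = off[["knee"]])
  expect_equal(unique(ja$hip), 0)
  expect_equal(unique(ja$knee), 0)
})
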