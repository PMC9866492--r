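#' Angle between two acceleration vectors (dot-product method)
#'
#' When a monitor is static its acceleration is the gravity vector expressed
#' in the monitor's local frame, so the angle between two monitors' filtered
#' acceleration vectors is the inter-segment angle. The angle is
#' `acos` of the normalized dot product, with the argument clamped to
#' [-1, 1]; it is symmetric in its arguments and invariant to positive
#' scaling of either vector.
#'
#' Samples where either vector's magnitude falls below `eps` (movement
#' transients, free fall) are degenerate: the direction is unreliable, so the
#' angle is returned as `NA` and downstream dwell tallies exclude the sample.
#'
#' @param a,b numeric length-3 vectors, or n x 3 matrices of row vectors,
#'   in g.
#' @param eps magnitude floor in g below which a vector is degenerate
#'   (default 0.2).
#' @return angle(s) in degrees in [0, 180]; `NA` where degenerate.
#' @export
vector_angle <- function(a, b, eps = 0.2) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(a) == nrow(b))
  na <- sqrt(rowSums(a * a))
  nb <- sqrt(rowSums(b * b))
  cosang <- rowSums(a * b) / (na * nb)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ang[na < eps | nb < eps] <- NA_real_
  ang
}

#' Per-sample hip and knee flexion angles during sedentary bouts
#'
#' Hip flexion is the angle between the torso and thigh gravity vectors; knee
#' flexion between thigh and shin. With the monitors mounted anteriorly and
#' mutually parallel, upright standing gives ~0 deg at both joints, so the
#' inter-gravity angle is the flexion angle relative to the anatomical
#' position without any axis permutation. Angles are evaluated only at
#' samples inside sedentary bouts; degenerate samples (see [vector_angle()])
#' are kept and flagged rather than dropped.
#'
#' @param torso,thigh,shin aligned, low-pass-filtered [accel_trace()]s.
#' @param bouts a `"sedentary_bouts"` data.frame from [extract_bouts()].
#' @param eps degenerate-vector magnitude floor in g.
#' @param hip_offset,knee_offset mounting-offset corrections in degrees,
#'   subtracted from the raw angles and floored at 0 (see
#'   [mounting_offsets()]); default 0 (off).
#' @return a data.frame of class `"joint_angles"` with columns `time`
#'   (seconds since the recording's first midnight), `hip`, `knee` (degrees),
#'   `bout_id` and `degenerate` (logical). Times are strictly increasing and
#'   each sample belongs to exactly one bout.
#' @export
joint_angles <- function(torso, thigh, shin, bouts, eps = 0.2,
                         hip_offset = 0, knee_offset = 0) {
  stopifnot(inherits(torso, "accel_trace"), inherits(thigh, "accel_trace"),
            inherits(shin, "accel_trace"))
  n <- nrow(thigh$xyz)
  if (nrow(torso$xyz) != n || nrow(shin$xyz) != n)
    stop("traces are not aligned; call align_traces() first", call. = FALSE)
  fs <- thigh$sample_rate
  t0 <- thigh$start_offset
  span_end <- t0 + n / fs
  if (nrow(bouts) == 0)
    return(structure(data.frame(time = numeric(0), hip = numeric(0),
                                knee = numeric(0), bout_id = integer(0),
                                degenerate = logical(0)),
                     class = c("joint_angles", "data.frame")))
  if (any(bouts$start < t0 - 1e-9) || any(bouts$end > span_end + 1e-9))
    stop("coverage error: bout [", sprintf("%.1f", bouts$start[1]),
         ", ...) extends outside the trace span [", t0, ", ",
         sprintf("%.1f", span_end), ")", call. = FALSE)
  # sample i (1-based) is at t0 + (i-1)/fs; half-open bout intervals
  idx_list <- lapply(seq_len(nrow(bouts)), function(k) {
    lo <- ceiling((bouts$start[k] - t0) * fs - 1e-9) + 1
    hi <- ceiling((bouts$end[k] - t0) * fs - 1e-9)
    if (hi < lo) integer(0) else lo:hi
  })
  idx <- unlist(idx_list)
  bout_id <- rep(bouts$bout_id, lengths(idx_list))
  hip <- vector_angle(torso$xyz[idx, , drop = FALSE],
                      thigh$xyz[idx, , drop = FALSE], eps = eps)
  knee <- vector_angle(thigh$xyz[idx, , drop = FALSE],
                       shin$xyz[idx, , drop = FALSE], eps = eps)
  degenerate <- is.na(hip) | is.na(knee)
  if (hip_offset != 0) hip <- pmax(hip - hip_offset, 0)
  if (knee_offset != 0) knee <- pmax(knee - knee_offset, 0)
  out <- data.frame(time = t0 + (idx - 1) / fs, hip = hip, knee = knee,
                    bout_id = bout_id, degenerate = degenerate)
  attr(out, "sample_rate") <- fs
  class(out) <- c("joint_angles", "data.frame")
  out
}

#' Mounting-offset estimate from upright time
#'
#' If the straps are slightly misaligned, the inter-monitor angle during
#' upright standing is not exactly 0. The median hip and knee angle over
#' upright events estimates that mounting offset; subtracting it (floored at
#' 0 deg) is an optional correction, off by default.
#'
#' @param torso,thigh,shin aligned, filtered [accel_trace()]s.
#' @param events an `"activity_events"` data.frame ([read_events()]).
#' @param eps degenerate-vector floor in g.
#' @return named numeric vector `c(hip =, knee =)` in degrees.
#' @export
mounting_offsets <- function(torso, thigh, shin, events, eps = 0.2) {
  up <- events[events$activity == "upright", , drop = FALSE]
  if (nrow(up) == 0) return(c(hip = 0, knee = 0))
  fs <- thigh$sample_rate
  t0 <- thigh$start_offset
  n <- nrow(thigh$xyz)
  idx <- unlist(lapply(seq_len(nrow(up)), function(k) {
    lo <- max(ceiling((up$start[k] - t0) * fs - 1e-9) + 1, 1)
    hi <- min(ceiling((up$start[k] + up$duration[k] - t0) * fs - 1e-9), n)
    if (hi < lo) integer(0) else lo:hi
  }))
  if (length(idx) == 0) return(c(hip = 0, knee = 0))
  hip <- vector_angle(torso$xyz[idx, , drop = FALSE],
                      thigh$xyz[idx, , drop = FALSE], eps = eps)
  knee <- vector_angle(thigh$xyz[idx, , drop = FALSE],
                       shin$xyz[idx, , drop = FALSE], eps = eps)
  c(hip = stats::median(hip, na.rm = TRUE), knee = stats::median(knee, na.rm = TRUE))
}
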