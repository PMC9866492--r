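#' Low-pass filter specification
#'
#' The gravity component of a body-worn accelerometer signal is isolated with
#' a first-order digital Butterworth low-pass at 0.18 Hz, applied forward and
#' backward (zero net phase shift). The two-pass amplitude response is the
#' square of the single-pass response, so the effective attenuation at
#' frequency f is `1 / (1 + (tan(pi f / fs) / tan(pi fc / fs))^2)`.
#'
#' @param cutoff cutoff frequency in Hz (default 0.18).
#' @param order filter order (default 1).
#' @param pad_factor length of the reflective edge padding, in filter time
#'   constants (`fs / (2 pi cutoff)` samples each). Must be at least 3; the
#'   default 25 makes the residual edge transient on a constant signal
#'   smaller than 1e-10 relative.
#' @return an object of class `"filter_spec"`.
#' @export
filter_spec <- function(cutoff = 0.18, order = 1, pad_factor = 25) {
  stopifnot(cutoff > 0, order >= 1, pad_factor >= 3)
  structure(list(cutoff = cutoff, order = as.integer(order),
                 pad_factor = pad_factor, zero_lag = TRUE),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> order-%d zero-lag Butterworth, cutoff %g Hz, pad %g tau\n",
              x$order, x$cutoff, x$pad_factor))
  invisible(x)
}

#' Theoretical two-pass amplitude response of the default filter
#'
#' Exact closed form for the forward-backward first-order digital Butterworth
#' (bilinear design): the single-pass power response evaluated at the warped
#' frequency. For `f << fs` this reduces to the analog form
#' `1 / (1 + (f / cutoff)^2)`.
#'
#' @param f frequency in Hz.
#' @param fs sampling frequency in Hz.
#' @param cutoff cutoff frequency in Hz.
#' @return amplitude gain of the two-pass filter at `f` (dimensionless).
#' @export
lowpass_gain <- function(f, fs, cutoff = 0.18) {
  1 / (1 + (tan(pi * f / fs) / tan(pi * cutoff / fs))^2)
}

# single-pass IIR: direct-form filtering via stats::filter (C level)
apply_iir <- function(b, a, x) {
  nb <- length(b)
  xb <- as.numeric(stats::filter(c(rep(0, nb - 1), x), b,
                                 method = "convolution", sides = 1))
  if (nb > 1) xb <- xb[-seq_len(nb - 1)]
  if (length(a) > 1) as.numeric(stats::filter(xb, -a[-1], method = "recursive"))
  else xb
}

# forward-backward filtering of one channel with odd-reflective edge padding
filtfilt_reflect <- function(bf, x, pad) {
  n <- length(x)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- apply_iir(bf$b, bf$a, xp)
  y <- rev(apply_iir(bf$b, bf$a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-lag low-pass filtering of an acceleration trace
#'
#' Each axis is filtered forward and then backward with the Butterworth
#' filter described by `spec`, after odd-reflective padding of
#' `spec$pad_factor` time constants at both ends. The result has zero net
#' phase shift, unit DC gain (a constant trace is returned unchanged to
#' within floating-point error) and the same length as the input.
#'
#' @param trace an [accel_trace()].
#' @param spec a [filter_spec()].
#' @return the filtered [accel_trace()].
#' @export
lowpass <- function(trace, spec = filter_spec()) {
  stopifnot(inherits(trace, "accel_trace"), inherits(spec, "filter_spec"))
  fs <- trace$sample_rate
  if (spec$cutoff >= fs / 2)
    stop("cutoff must be below the Nyquist frequency ", fs / 2, " Hz", call. = FALSE)
  tau <- fs / (2 * pi * spec$cutoff)               # time constant in samples
  pad <- ceiling(spec$pad_factor * tau)
  n <- nrow(trace$xyz)
  if (n <= pad)
    stop("input too short: trace has ", n, " samples but the filter needs more than ",
         pad, " (", sprintf("%.1f", pad / fs), " s) for its edge padding", call. = FALSE)
  bf <- signal::butter(spec$order, spec$cutoff / (fs / 2), type = "low")
  out <- trace
  for (j in 1:3) out$xyz[, j] <- filtfilt_reflect(bf, trace$xyz[, j], pad)
  out
}

#' Align the three monitor traces on a shared sample index
#'
#' All monitors are started simultaneously, so alignment only has to check
#' that the clocks agree and truncate to the shortest common length. Traces
#' are never reordered or interpolated.
#'
#' @param torso,thigh,shin [accel_trace()] objects.
#' @param tol maximum allowed start-time mismatch in seconds (default one
#'   sample period).
#' @return a named list of the three traces, truncated to a common length;
#'   a warning reports how many samples were dropped.
#' @export
align_traces <- function(torso, thigh, shin, tol = NULL) {
  traces <- list(torso = torso, thigh = thigh, shin = shin)
  fs <- vapply(traces, function(t) t$sample_rate, numeric(1))
  if (length(unique(fs)) != 1)
    stop("configuration error: traces have differing sample rates (",
         paste(fs, collapse = ", "), ")", call. = FALSE)
  if (is.null(tol)) tol <- 1 / fs[1]
  offs <- vapply(traces, function(t) t$start_offset, numeric(1))
  if (max(offs) - min(offs) > tol + 1e-9)
    stop("alignment error: trace start times differ by ",
         sprintf("%.2f", max(offs) - min(offs)), " s (tolerance ",
         sprintf("%.3f", tol), " s)", call. = FALSE)
  lens <- vapply(traces, function(t) nrow(t$xyz), integer(1))
  m <- min(lens)
  dropped <- sum(lens - m)
  if (dropped > 0) {
    warning("align: truncated traces to ", m, " samples (dropped ", dropped,
            " samples total)", call. = FALSE)
    traces <- lapply(traces, function(t) {
      t$xyz <- t$xyz[seq_len(m), , drop = FALSE]
      t
    })
  }
  traces
}
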