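#' Convert raw sensor counts to acceleration in g
#'
#' Both supported device generations store acceleration as unsigned integer
#' counts; the calibration is a symmetric linear map whose midpoint count is
#' exactly 0 g (see [ap_dialect()] for the default coefficients).
#'
#' @param raw integer counts.
#' @param version `"AP3"` (8-bit, +/-2 g) or `"AP4"` (10-bit, +/-4 g).
#' @param dialect an [ap_dialect()] carrying the count-map coefficients.
#' @return numeric acceleration in g, same length as `raw`.
#' @export
counts_to_g <- function(raw, version = c("AP3", "AP4"), dialect = ap_dialect()) {
  version <- match.arg(version)
  m <- dialect$count_maps[[version]]
  hi <- 2^m$bits - 1
  if (any(!is.finite(raw)) || any(raw < 0 | raw > hi))
    stop("count out of range [0, ", hi, "] for ", version, call. = FALSE)
  (raw - m$offset) / m$scale
}

#' Quantize acceleration in g to raw sensor counts
#'
#' Inverse of [counts_to_g()] with rounding to the nearest representable
#' count and clamping at the device range, so that
#' `counts_to_g(g_to_counts(x))` is the device quantization of `x` and
#' round-trips are bit-exact on already-quantized values.
#'
#' @inheritParams counts_to_g
#' @param g numeric acceleration in g.
#' @return integer counts.
#' @export
g_to_counts <- function(g, version = c("AP3", "AP4"), dialect = ap_dialect()) {
  version <- match.arg(version)
  m <- dialect$count_maps[[version]]
  hi <- 2^m$bits - 1
  as.integer(pmin(pmax(round(g * m$scale + m$offset), 0), hi))
}

#' Construct an acceleration trace
#'
#' A trace is one monitor's uniformly sampled triaxial acceleration in g.
#' Sample `i` (1-based) occurs at `start_offset + (i - 1)/sample_rate` seconds
#' after midnight of `start_date`; all monitors of a recording are started
#' simultaneously at that midnight, so times are comparable across sites.
#'
#' @param xyz numeric matrix with n rows and 3 columns (x, y, z) in g.
#' @param site monitor placement: `"torso"`, `"thigh"` or `"shin"`.
#' @param sample_rate samples per second (default 20).
#' @param start_date calendar date of the recording's first midnight.
#' @param start_offset seconds between that midnight and the first sample.
#' @param device_version `"AP3"` or `"AP4"`.
#' @return an object of class `"accel_trace"`.
#' @export
accel_trace <- function(xyz, site = c("torso", "thigh", "shin"),
                        sample_rate = 20, start_date = as.Date("2023-01-02"),
                        start_offset = 0, device_version = c("AP3", "AP4")) {
  site <- match.arg(site)
  device_version <- match.arg(device_version)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have three columns", call. = FALSE)
  if (!all(is.finite(xyz))) stop("acceleration values must be finite", call. = FALSE)
  storage.mode(xyz) <- "double"
  colnames(xyz) <- c("x", "y", "z")
  structure(list(xyz = xyz, site = site, sample_rate = sample_rate,
                 start_date = as.Date(start_date), start_offset = start_offset,
                 device_version = device_version),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  n <- nrow(x$xyz)
  cat(sprintf("<accel_trace> %s, %s, %d samples @ %g Hz (%.1f h), start %s +%gs\n",
              x$site, x$device_version, n, x$sample_rate,
              n / x$sample_rate / 3600, format(x$start_date), x$start_offset))
  invisible(x)
}

#' Sample times of a trace, in seconds since the recording's first midnight
#' @param trace an [accel_trace()].
#' @return numeric vector of length `nrow(trace$xyz)`.
#' @export
trace_times <- function(trace) {
  trace$start_offset + (seq_len(nrow(trace$xyz)) - 1) / trace$sample_rate
}

#' Read a raw triaxial acceleration file
#'
#' Reads one monitor's comma-separated raw export: a time column (seconds
#' since the recording's first midnight) and three integer count columns,
#' named per the dialect. Counts are converted to g with [counts_to_g()].
#'
#' @param path path to the CSV file.
#' @param site monitor placement the file belongs to.
#' @param version device version, `"AP3"` or `"AP4"`.
#' @param dialect an [ap_dialect()]; defaults cover the canonical export.
#' @param sample_rate sampling frequency in Hz (default 20).
#' @param start_date recording start date (metadata only).
#' @return an [accel_trace()].
#' @export
read_accel <- function(path, site = c("torso", "thigh", "shin"),
                       version = c("AP3", "AP4"), dialect = ap_dialect(),
                       sample_rate = 20, start_date = as.Date("2023-01-02")) {
  site <- match.arg(site)
  version <- match.arg(version)
  if (!file.exists(path)) stop("acceleration file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, showProgress = FALSE)
  if (nrow(dt) == 0) stop("empty acceleration file: ", path, call. = FALSE)
  cols <- dialect$accel_cols
  missing_cols <- setdiff(unname(cols), names(dt))
  if (length(missing_cols) > 0)
    stop("dialect error: missing column(s) ", paste(missing_cols, collapse = ", "),
         " in ", path, call. = FALSE)
  num <- function(role) {
    v <- dt[[cols[[role]]]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(as.character(v)))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop("format error: non-numeric value in column '", cols[[role]],
           "' at data row ", bad[1], " of ", path, call. = FALSE)
    v
  }
  tm <- num("time")
  if (is.unsorted(tm, strictly = TRUE))
    stop("format error: timestamps not strictly increasing in ", path, call. = FALSE)
  counts <- cbind(num("x"), num("y"), num("z"))
  if (any(counts != round(counts)))
    stop("format error: non-integer count in ", path, call. = FALSE)
  accel_trace(counts_to_g(counts, version, dialect), site = site,
              sample_rate = sample_rate, start_date = start_date,
              start_offset = tm[1], device_version = version)
}

#' Write a raw triaxial acceleration file
#'
#' Inverse of [read_accel()]: quantizes the trace through the device count
#' map and writes the canonical comma-separated layout, so
#' `read_accel(write_accel(x))` round-trips exactly for traces that are
#' already on the device grid.
#'
#' @param trace an [accel_trace()].
#' @param path output CSV path.
#' @param dialect an [ap_dialect()].
#' @return `path`, invisibly.
#' @export
write_accel <- function(trace, path, dialect = ap_dialect()) {
  stopifnot(inherits(trace, "accel_trace"))
  counts <- g_to_counts(trace$xyz, trace$device_version, dialect)
  dim(counts) <- dim(trace$xyz)
  cols <- dialect$accel_cols
  dt <- data.table::data.table(time = trace_times(trace),
                               x = counts[, 1], y = counts[, 2], z = counts[, 3])
  data.table::setnames(dt, c(cols[["time"]], cols[["x"]], cols[["y"]], cols[["z"]]))
  data.table::fwrite(dt, path, showProgress = FALSE)
  invisible(path)
}
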