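#' File dialect configuration
#'
#' Vendor exports of raw acceleration and events tables vary in column naming
#' and activity coding across software versions. A dialect bundles the column
#' maps, the activity-code map, and the count-to-g calibration coefficients so
#' that readers and writers agree bit-for-bit.
#'
#' The default count maps are symmetric linear maps consistent with the device
#' ranges: an 8-bit +/-2 g device maps count c to (c - 127)/63 g and a 10-bit
#' +/-4 g device maps c to (c - 512)/128 g, so the count midpoint is exactly
#' 0 g in both.
#'
#' @param accel_cols named character vector mapping canonical accel column
#'   roles `time`, `x`, `y`, `z` to the column names found in the file.
#' @param events_cols named character vector mapping roles `start`,
#'   `duration`, `code` to column names in the events file.
#' @param diary_cols named character vector mapping roles `date`, `wake`,
#'   `sleep` to column names in the diary file.
#' @param activity_codes named list mapping activity classes (`sedentary`,
#'   `upright`) to the integer codes used in the events file. Codes not
#'   covered map to class `"other"` with a warning.
#' @param count_maps named list with entries `AP3` and `AP4`, each a list
#'   `list(offset =, scale =, bits =)` defining g = (count - offset)/scale and
#'   the admissible count range [0, 2^bits - 1].
#' @return an object of class `"ap_dialect"`.
#' @export
ap_dialect <- function(accel_cols = c(time = "time", x = "x", y = "y", z = "z"),
                       events_cols = c(start = "start", duration = "duration",
                                       code = "activity_code"),
                       diary_cols = c(date = "date", wake = "wake", sleep = "sleep"),
                       activity_codes = list(sedentary = 0L, upright = 1L),
                       count_maps = list(
                         AP3 = list(offset = 127, scale = 63, bits = 8L),
                         AP4 = list(offset = 512, scale = 128, bits = 10L))) {
  need <- function(x, roles, what) {
    if (!all(roles %in% names(x)))
      stop("dialect ", what, " must name roles: ", paste(roles, collapse = ", "),
           call. = FALSE)
  }
  need(accel_cols, c("time", "x", "y", "z"), "accel_cols")
  need(events_cols, c("start", "duration", "code"), "events_cols")
  need(diary_cols, c("date", "wake", "sleep"), "diary_cols")
  need(activity_codes, c("sedentary", "upright"), "activity_codes")
  need(count_maps, c("AP3", "AP4"), "count_maps")
  for (v in c("AP3", "AP4"))
    need(count_maps[[v]], c("offset", "scale", "bits"), paste0("count_maps$", v))
  structure(list(accel_cols = accel_cols, events_cols = events_cols,
                 diary_cols = diary_cols, activity_codes = activity_codes,
                 count_maps = count_maps),
            class = "ap_dialect")
}

#' Read a dialect configuration from a YAML key-value file
#'
#' Any key omitted from the file keeps its default from [ap_dialect()].
#'
#' @param path path to a YAML file with (a subset of) the keys of
#'   [ap_dialect()].
#' @return an `"ap_dialect"` object.
#' @export
read_dialect <- function(path) {
  if (!file.exists(path)) stop("dialect file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  def <- ap_dialect()
  args <- list()
  for (key in c("accel_cols", "events_cols", "diary_cols")) {
    if (!is.null(raw[[key]])) {
      v <- unlist(raw[[key]])
      # YAML 1.1 reads a bare key `y`/`n` as a boolean; map it back
      names(v)[names(v) == "TRUE"] <- "y"
      names(v)[names(v) == "FALSE"] <- "n"
      full <- def[[key]]
      full[names(v)] <- v
      args[[key]] <- full
    }
  }
  if (!is.null(raw$activity_codes))
    args$activity_codes <- utils::modifyList(
      def$activity_codes, lapply(raw$activity_codes, as.integer))
  if (!is.null(raw$count_maps)) {
    cm <- def$count_maps
    for (v in names(raw$count_maps)) cm[[v]] <- utils::modifyList(cm[[v]], raw$count_maps[[v]])
    args$count_maps <- cm
  }
  merged <- utils::modifyList(unclass(def), args)
  do.call(ap_dialect, merged)
}

#' @export
print.ap_dialect <- function(x, ...) {
  cat("<ap_dialect>\n")
  cat("  accel columns: ", paste(names(x$accel_cols), x$accel_cols, sep = "=",
                                 collapse = ", "), "\n")
  cat("  events columns:", paste(names(x$events_cols), x$events_cols, sep = "=",
                                 collapse = ", "), "\n")
  cat("  activity codes:", paste(names(x$activity_codes), unlist(x$activity_codes),
                                 sep = "=", collapse = ", "), "\n")
  for (v in names(x$count_maps)) {
    m <- x$count_maps[[v]]
    cat(sprintf("  %s: g = (count - %g)/%g, %d-bit\n", v, m$offset, m$scale, m$bits))
  }
  invisible(x)
}
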