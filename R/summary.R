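#' Per-participant daily posture summary (minutes per day)
#'
#' Converts per-day posture dwell to minutes, fills in the full
#' day x posture x class grid (a day without any prolonged bout contributes
#' 0 min to the prolonged figures), adds `total = prolonged + non_prolonged`
#' and averages across valid days. A valid day is a diary day; no minimum
#' wear-time filter is applied by default since the monitors are worn 24 h.
#'
#' @param dwell output of [posture_dwell()].
#' @param diary the `"wear_diary"` defining valid days.
#' @param participant_id identifier carried into the result.
#' @return an object of class `"posture_summary"`: list with `participant_id`,
#'   `days` (long data.frame of minutes per day, posture and class including
#'   `total`), `means` (3 x 3 matrix, postures x classes, min/day) and
#'   `valid_days`.
#' @export
daily_summary <- function(dwell, diary, participant_id = "P1") {
  valid <- diary$date
  if (length(valid) == 0) stop("empty-summary error: no valid days", call. = FALSE)
  postures <- c("lying", "bent_sit", "straight_sit")
  classes <- c("prolonged", "non_prolonged")
  grid <- expand.grid(date = valid, posture = postures, class = classes,
                      stringsAsFactors = FALSE)
  key <- function(d, p, cl) paste(format(d), p, cl)
  mins <- numeric(nrow(grid))
  if (nrow(dwell) > 0) {
    got <- tapply(dwell$dwell_s, key(dwell$date, dwell$posture, dwell$class), sum)
    hit <- got[key(grid$date, grid$posture, grid$class)]
    mins <- ifelse(is.na(hit), 0, hit) / 60
  }
  grid$minutes <- mins
  tot <- stats::aggregate(minutes ~ date + posture, data = grid, FUN = sum)
  tot$class <- "total"
  days <- rbind(grid[, c("date", "posture", "class", "minutes")],
                tot[, c("date", "posture", "class", "minutes")])
  days$posture <- factor(days$posture, levels = postures)
  days$class <- factor(days$class, levels = c(classes, "total"))
  days <- days[order(days$date, days$posture, days$class), ]
  rownames(days) <- NULL
  means <- with(days, tapply(minutes, list(posture, class), mean))
  structure(list(participant_id = participant_id, days = days,
                 means = means, valid_days = length(valid)),
            class = "posture_summary")
}

#' @export
print.posture_summary <- function(x, ...) {
  cat(sprintf("<posture_summary> participant %s, %d valid day(s); min/day:\n",
              x$participant_id, x$valid_days))
  print(round(x$means, 1))
  invisible(x)
}

# paired Wilcoxon signed-rank with the standard zero/tie treatment:
# zero differences dropped; exact p for <= 25 informative pairs without ties,
# otherwise normal approximation with continuity correction
paired_wilcoxon <- function(x, y, exact_max = 25) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p = NA_real_, n = 0L,
                method = "undefined (all differences zero)"))
  ties <- any(duplicated(abs(d)))
  exact <- n <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, paired = FALSE,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = n,
       method = if (exact) "exact" else "normal approximation")
}

#' Group comparison of posture times across participants
#'
#' Reproduces the cohort-level analysis: Shapiro-Wilk normality per variable,
#' then paired two-sided Wilcoxon signed-rank tests for (i) the three
#' pairwise posture contrasts on total min/day, judged at the
#' Bonferroni-adjusted alpha `family_alpha / 3`, and (ii) prolonged vs
#' non-prolonged time within each posture, judged at the same adjusted alpha.
#'
#' @param summaries list of `"posture_summary"` objects, one per participant.
#' @param family_alpha family-wise alpha (default 0.05).
#' @return an object of class `"posture_stats"`: list with `shapiro`
#'   (data.frame of W and p per variable), `posture_tests` and
#'   `class_tests` (data.frames of Wilcoxon results with a `significant`
#'   flag), `alpha_family`, `alpha_adjusted`, `n_participants`.
#' @export
compare_groups <- function(summaries, family_alpha = 0.05) {
  n <- length(summaries)
  if (n < 6)
    warning("fewer than 6 participants; tests computed but weakly powered",
            call. = FALSE)
  postures <- c("lying", "bent_sit", "straight_sit")
  classes <- c("prolonged", "non_prolonged", "total")
  vals <- array(NA_real_, dim = c(n, 3, 3),
                dimnames = list(NULL, postures, classes))
  for (i in seq_len(n)) vals[i, , ] <- summaries[[i]]$means[postures, classes]
  alpha_adj <- family_alpha / 3

  sw <- do.call(rbind, lapply(postures, function(p) {
    do.call(rbind, lapply(classes, function(cl) {
      x <- vals[, p, cl]
      ok <- n >= 3 && n <= 5000 && stats::sd(x) > 0
      t <- if (ok) stats::shapiro.test(x) else list(statistic = NA, p.value = NA)
      data.frame(variable = paste(p, cl, sep = "."),
                 W = unname(t$statistic), p = t$p.value)
    }))
  }))

  contrasts <- list(c("bent_sit", "straight_sit"), c("bent_sit", "lying"),
                    c("straight_sit", "lying"))
  posture_tests <- do.call(rbind, lapply(contrasts, function(ct) {
    r <- paired_wilcoxon(vals[, ct[1], "total"], vals[, ct[2], "total"])
    data.frame(contrast = paste(ct[1], "vs", ct[2]), statistic = r$statistic,
               p = r$p, n_pairs = r$n, method = r$method,
               significant = !is.na(r$p) & r$p < alpha_adj)
  }))
  class_tests <- do.call(rbind, lapply(postures, function(p) {
    r <- paired_wilcoxon(vals[, p, "prolonged"], vals[, p, "non_prolonged"])
    data.frame(contrast = paste0(p, ": prolonged vs non_prolonged"),
               statistic = r$statistic, p = r$p, n_pairs = r$n,
               method = r$method,
               significant = !is.na(r$p) & r$p < alpha_adj)
  }))
  structure(list(shapiro = sw, posture_tests = posture_tests,
                 class_tests = class_tests, alpha_family = family_alpha,
                 alpha_adjusted = alpha_adj, n_participants = n),
            class = "posture_stats")
}

#' @export
print.posture_stats <- function(x, ...) {
  cat(sprintf("<posture_stats> %d participants; alpha %g / 3 = %.4f (printed: %.3f)\n",
              x$n_participants, x$alpha_family, x$alpha_adjusted,
              round(x$alpha_adjusted, 3)))
  cat("Posture contrasts (total min/day):\n")
  print(x$posture_tests, row.names = FALSE, digits = 4)
  cat("Prolonged vs non-prolonged within posture:\n")
  print(x$class_tests, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Participant-level means as a matrix
#'
#' @param summaries list of `"posture_summary"` objects.
#' @param class which bout-length class to extract (default `"total"`).
#' @return numeric matrix participants x postures, min/day.
#' @export
cohort_matrix <- function(summaries, class = "total") {
  postures <- c("lying", "bent_sit", "straight_sit")
  out <- t(vapply(summaries, function(s) s$means[postures, class], numeric(3)))
  colnames(out) <- postures
  rownames(out) <- vapply(summaries, function(s) as.character(s$participant_id),
                          character(1))
  out
}
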