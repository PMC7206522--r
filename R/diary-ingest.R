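# Raw diary logs -> aligned per-patient daily series of the three analysis
# variables (time in bed, total sleep time, depression core-symptom score),
# plus the study inclusion filter.

#' Time in bed from diary clock times
#'
#' Elapsed minutes from going to bed to the next occurrence of the get-up
#' time; bed intervals crossing midnight wrap over 24 h. Missing inputs
#' propagate to a missing result.
#'
#' @param go_to_bed,get_up clock times as "HH:MM" strings (vectorised).
#' @return minutes in bed, in (0, 1440].
#' @examples
#' time_in_bed("23:30", "07:00")  # 450
#' time_in_bed("12:00", "11:00")  # 1380: get-up read as the next day
#' @export
time_in_bed <- function(go_to_bed, get_up) {
  bed <- parse_clock(go_to_bed)
  up <- parse_clock(get_up)
  tib <- (up - bed) %% 1440
  zero <- !is.na(tib) & tib == 0
  if (any(zero)) {
    stop("go_to_bed equals get_up at position(s) ",
         paste(which(zero), collapse = ", "),
         ": a zero-length bed interval is an invalid diary entry")
  }
  tib
}

#' Depression core-symptom score from the two evening items
#'
#' The daily score is the arithmetic mean of the two 0-10 visual-analogue
#' items (interest/pleasure; depressed/hopeless), kept at full precision.
#' If either item is missing the score is missing: there is no
#' single-item fallback.
#'
#' @param item_interest,item_mood item ratings in \[0, 10\] (vectorised).
#' @return the mean score, or `NA` where either item is absent.
#' @export
depression_score <- function(item_interest, item_mood) {
  bad <- function(x) !is.na(x) & (x < 0 | x > 10)
  if (any(bad(item_interest)) || any(bad(item_mood))) {
    stop("depression items must lie in [0, 10]")
  }
  out <- (item_interest + item_mood) / 2
  out[is.na(item_interest) | is.na(item_mood)] <- NA_real_
  out
}

#' Align raw diary logs into a daily patient series
#'
#' Produces one row per calendar day from the first to the last logged
#' date, deriving time in bed from the clock times, taking total sleep
#' time from the reported minutes slept, and the depression score from
#' the two evening items. Gap days appear as all-missing rows. Days on
#' which the reported sleep minutes exceed the derived time in bed are
#' internally inconsistent and have both sleep variables set missing
#' (recorded in the `invalid_days` attribute).
#'
#' The temporal convention: the night of sleep reported in the morning
#' log of day t and the depression rating given in the evening of day t
#' share index t, so the night's sleep precedes the same day's rating.
#'
#' @param logs a `diary_log` data frame for a single patient, rows in any
#'   order.
#' @return a `data.frame` of class `patient_series` with columns
#'   `patient_id`, `date`, `tib_min`, `tst_min`, `dep_score`.
#' @export
align_series <- function(logs) {
  logs <- as.data.frame(logs)
  if (nrow(logs) == 0L) stop("no diary rows")
  ids <- unique(logs$patient_id)
  if (length(ids) != 1L) {
    stop("align_series expects one patient, got: ",
         paste(ids, collapse = ", "))
  }
  logs$date <- as.Date(logs$date)
  dup <- unique(logs$date[duplicated(logs$date)])
  if (length(dup)) {
    stop("duplicate diary dates for patient ", ids, ": ",
         paste(format(dup), collapse = ", "))
  }
  days <- seq(min(logs$date), max(logs$date), by = "day")
  idx <- match(days, logs$date)

  tib <- time_in_bed(logs$go_to_bed[idx], logs$get_up[idx])
  tst <- as.numeric(logs$sleep_minutes[idx])
  dep <- depression_score(logs$item_interest[idx], logs$item_mood[idx])

  bad_sleep <- !is.na(tst) & tst < 0
  if (any(bad_sleep)) stop("negative sleep_minutes")
  invalid <- !is.na(tib) & !is.na(tst) & tst > tib
  tib[invalid] <- NA_real_
  tst[invalid] <- NA_real_

  out <- data.frame(patient_id = ids, date = days, tib_min = tib,
                    tst_min = tst, dep_score = dep,
                    stringsAsFactors = FALSE)
  class(out) <- c("patient_series", "data.frame")
  attr(out, "invalid_days") <- days[invalid]
  out
}

#' Per-variable missing fractions of a patient series
#'
#' @param series a `patient_series`.
#' @return named numeric vector of missing fractions for `tib_min`,
#'   `tst_min`, `dep_score`.
#' @export
missing_fractions <- function(series) {
  vapply(series[c("tib_min", "tst_min", "dep_score")],
         function(v) mean(is.na(v)), numeric(1))
}

#' Study inclusion filter
#'
#' A patient enters the analysis only with a continuous collection period
#' of at least `min_days` days and no analysis variable missing on more
#' than `max_missing_frac` of the days.
#'
#' @param series a `patient_series`.
#' @param min_days minimum series length in days (default 130).
#' @param max_missing_frac maximum tolerated per-variable missing
#'   fraction (default 0.30).
#' @return list of class `inclusion_decision`: `include` (logical),
#'   `n_days`, `missing_frac` (per variable), `reasons` (character,
#'   empty when included).
#' @export
inclusion_filter <- function(series, min_days = 130L,
                             max_missing_frac = 0.30) {
  n <- nrow(series)
  mf <- missing_fractions(series)
  reasons <- character(0)
  if (n < min_days) {
    reasons <- c(reasons, sprintf("collection period %d days < %d", n,
                                  as.integer(min_days)))
  }
  over <- mf > max_missing_frac
  if (any(over)) {
    reasons <- c(reasons, sprintf("%s missing %.1f%% > %.0f%%",
                                  names(mf)[over], 100 * mf[over],
                                  100 * max_missing_frac))
  }
  structure(list(include = length(reasons) == 0L, n_days = n,
                 missing_frac = mf, reasons = reasons),
            class = "inclusion_decision")
}

#' @export
print.inclusion_decision <- function(x, ...) {
  cat(if (x$include) "INCLUDE" else "EXCLUDE", " (", x$n_days, " days; ",
      paste(sprintf("%s %.1f%%", names(x$missing_frac),
                    100 * x$missing_frac), collapse = ", "), ")\n", sep = "")
  if (length(x$reasons)) cat("  ", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Write an aligned patient series to CSV
#'
#' @param series a `patient_series`.
#' @param path output path.
#' @export
write_series <- function(series, path) {
  x <- as.data.frame(series)
  x$date <- format(x$date, "%Y-%m-%d")
  utils::write.csv(x, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
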