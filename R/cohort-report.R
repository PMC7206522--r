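# Cohort-level aggregation: association counts by model, direction and
# sign; absolute-value mean rows for cumulative IRF and FEVD tables;
# cohort descriptives; and the end-to-end per-patient / cohort drivers.

#' Classify per-patient Granger results into an association table
#'
#' Counts significant associations by model, direction and sign. A
#' patient-model with both directions significant is counted once in the
#' "mutual" row (with a sign only when both directions agree), not in
#' the single-direction rows.
#'
#' @param results data frame with one row per patient-model-direction:
#'   columns `patient_id`, `model`, `direction`
#'   (`"sleep_to_dep"`/`"dep_to_sleep"`), `significant` (logical),
#'   `sign` (`"positive"`/`"negative"`).
#' @return data frame of class `association_summary` with columns
#'   `model`, `direction` (the two directions plus `"mutual"`),
#'   `positive_n`, `negative_n`, `total_n`.
#' @export
classify_associations <- function(results) {
  dirs <- c("sleep_to_dep", "dep_to_sleep", "mutual")
  models <- unique(results$model)
  if (length(models) == 0L) models <- character(0)
  out <- expand.grid(model = models, direction = dirs,
                     stringsAsFactors = FALSE)
  out$positive_n <- rep(0L, nrow(out))
  out$negative_n <- rep(0L, nrow(out))
  out$total_n <- rep(0L, nrow(out))
  bump <- function(model, direction, sign) {
    r <- which(out$model == model & out$direction == direction)
    out$total_n[r] <<- out$total_n[r] + 1L
    if (identical(sign, "positive")) {
      out$positive_n[r] <<- out$positive_n[r] + 1L
    } else if (identical(sign, "negative")) {
      out$negative_n[r] <<- out$negative_n[r] + 1L
    }
  }
  for (m in models) {
    sub <- results[results$model == m, , drop = FALSE]
    for (pid in unique(sub$patient_id)) {
      pr <- sub[sub$patient_id == pid, , drop = FALSE]
      s2d <- pr[pr$direction == "sleep_to_dep", , drop = FALSE]
      d2s <- pr[pr$direction == "dep_to_sleep", , drop = FALSE]
      sig_s2d <- nrow(s2d) > 0L && isTRUE(s2d$significant[1L])
      sig_d2s <- nrow(d2s) > 0L && isTRUE(d2s$significant[1L])
      if (sig_s2d && sig_d2s) {
        sg <- if (identical(s2d$sign[1L], d2s$sign[1L])) s2d$sign[1L]
        bump(m, "mutual", sg)
      } else if (sig_s2d) {
        bump(m, "sleep_to_dep", s2d$sign[1L])
      } else if (sig_d2s) {
        bump(m, "dep_to_sleep", d2s$sign[1L])
      }
    }
  }
  class(out) <- c("association_summary", "data.frame")
  out
}

#' Mean of absolute values, table-rounded
#'
#' The aggregation convention of the cohort summary tables: per-patient
#' cumulative responses (which carry signs) are averaged in magnitude,
#' then rounded half-up to 2 decimals as printed. Signed means are
#' available via `signed = TRUE`.
#'
#' @param values per-patient numbers for one table cell (>= 1 value).
#' @param signed average signed values instead of magnitudes.
#' @param digits decimals for half-up rounding (default 2).
#' @return the rounded mean.
#' @examples
#' aggregate_abs_mean(c(7.46, 8.42, 12.74, -7.16))  # 8.95
#' @export
aggregate_abs_mean <- function(values, signed = FALSE, digits = 2L) {
  if (length(values) == 0L) stop("no values to aggregate")
  v <- if (signed) values else abs(values)
  round_half_up(mean(v), digits)
}

#' Cohort descriptives
#'
#' @param table data frame with one row per patient and columns `days`,
#'   `sex`, `age`.
#' @return list of class `cohort_descriptives`: `n_patients`,
#'   `mean_days` (half-up-rounded integer), `days_range` (min, max),
#'   `median_age`, `sex_counts`.
#' @export
cohort_descriptives <- function(table) {
  stopifnot(all(c("days", "sex", "age") %in% names(table)))
  structure(
    list(n_patients = nrow(table),
         mean_days = as.integer(round_half_up(mean(table$days), 0L)),
         days_range = range(table$days),
         median_age = stats::median(table$age),
         sex_counts = table(table$sex)),
    class = "cohort_descriptives")
}

#' @export
print.cohort_descriptives <- function(x, ...) {
  cat(x$n_patients, " patients (",
      paste(sprintf("%s: %d", names(x$sex_counts), as.integer(x$sex_counts)),
            collapse = ", "), ")\n", sep = "")
  cat("Collection period: mean ", x$mean_days, " days (range ",
      x$days_range[1L], "-", x$days_range[2L], ")\n", sep = "")
  cat("Median age: ", x$median_age, " years\n", sep = "")
  invisible(x)
}

#' Analyze one patient: impute, filter, fit, test, quantify
#'
#' The per-patient pipeline for one model: pick the sleep variable
#' (total sleep time for model `"tst"`, time in bed for `"tib"`), impute
#' each series by Kalman smoothing where needed, difference both to
#' stationarity, select the lag order by AIC (max 7), fit the bivariate
#' VAR, test Granger causality in both directions at `alpha`, and — for
#' significant directions — compute the 10-day cumulative orthogonalized
#' impulse response and the forecast-error variance decomposition.
#'
#' @param series a `patient_series` from [align_series()].
#' @param model `"tst"` or `"tib"`.
#' @param max_lag maximum candidate lag order (default 7 days).
#' @param alpha significance level (default 0.05).
#' @param H dynamics horizon in days (default 10).
#' @param boot attach bootstrap bands to the impulse responses.
#' @param runs,seed bootstrap settings (see [irf_bands()]).
#' @return list of class `patient_analysis`: `patient_id`, `model`,
#'   `fit`, `prep` (filter/imputation reports), `granger` (both
#'   directions), and `irf`/`fevd` for significant directions.
#' @export
analyze_patient <- function(series, model = c("tst", "tib"), max_lag = 7L,
                            alpha = 0.05, H = 10L, boot = FALSE,
                            runs = 500L, seed = NULL) {
  model <- match.arg(model)
  sleep_col <- if (model == "tst") "tst_min" else "tib_min"
  sleep_name <- if (model == "tst") "tst" else "tib"
  prep <- prepare_pair(series[[sleep_col]], series$dep_score,
                       var_names = c(sleep_name, "dep"))
  fit <- idiovar(prep$y, max_lag = max_lag)
  g <- list(
    sleep_to_dep = granger_test(fit, cause = sleep_name, effect = "dep",
                                alpha = alpha, horizon = H),
    dep_to_sleep = granger_test(fit, cause = "dep", effect = sleep_name,
                                alpha = alpha, horizon = H))
  out <- list(patient_id = series$patient_id[1L], model = model,
              fit = fit, prep = prep, granger = g,
              irf = list(), fevd = NULL)
  if (any(vapply(g, `[[`, logical(1), "significant"))) {
    for (dname in names(g)) {
      if (!g[[dname]]$significant) next
      cause <- g[[dname]]$cause
      effect <- g[[dname]]$effect
      out$irf[[dname]] <- irf(fit, impulse = cause, response = effect,
                              H = H, boot = boot, runs = runs, seed = seed)
    }
    out$fevd <- fevd(fit, H = H)
  }
  class(out) <- "patient_analysis"
  out
}

#' @export
print.patient_analysis <- function(x, ...) {
  cat("Patient ", x$patient_id, ", model ", toupper(x$model), ": VAR(",
      x$fit$p, ")\n", sep = "")
  for (g in x$granger) print(g)
  invisible(x)
}

#' Analyze a cohort end to end
#'
#' Applies the inclusion filter, runs [analyze_patient()] for every
#' included patient and requested model, and aggregates: the association
#' table by model/direction/sign, per-patient cumulative impulse
#' responses with their absolute-value mean rows, and FEVD shares with
#' mean rows.
#'
#' @param series_list list of `patient_series` (one per patient).
#' @param models models to fit (default both).
#' @param min_days,max_missing_frac inclusion thresholds
#'   (see [inclusion_filter()]).
#' @param ... passed to [analyze_patient()].
#' @return list of class `cohort_analysis`: `included`, `excluded` (with
#'   reasons), `analyses`, `results` (flat per-direction data frame),
#'   `associations` (classified counts).
#' @export
analyze_cohort <- function(series_list, models = c("tst", "tib"),
                           min_days = 130L, max_missing_frac = 0.30, ...) {
  decisions <- lapply(series_list, inclusion_filter, min_days = min_days,
                      max_missing_frac = max_missing_frac)
  inc <- vapply(decisions, `[[`, logical(1), "include")
  ids <- vapply(series_list, function(s) s$patient_id[1L], character(1))
  analyses <- list()
  rows <- list()
  for (i in which(inc)) {
    for (m in models) {
      a <- analyze_patient(series_list[[i]], model = m, ...)
      analyses[[paste(ids[i], m, sep = ".")]] <- a
      for (dname in names(a$granger)) {
        g <- a$granger[[dname]]
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = ids[i], model = toupper(m), direction = dname,
          p = a$fit$p, statistic = g$statistic, p_value = g$p_value,
          significant = g$significant, sign = g$association_sign,
          cumulative_irf_h10 = g$cumulative_irf,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  structure(
    list(included = ids[inc],
         excluded = lapply(decisions[!inc], `[[`, "reasons"),
         decisions = decisions, analyses = analyses, results = results,
         associations = if (!is.null(results)) {
           classify_associations(results)
         }),
    class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(length(x$included), "patient(s) included,",
      length(x$excluded), "excluded\n")
  if (!is.null(x$associations)) {
    cat("\nSignificant associations (counts):\n")
    print(as.data.frame(x$associations), row.names = FALSE)
  }
  invisible(x)
}
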