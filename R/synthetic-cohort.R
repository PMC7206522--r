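# Synthetic diary cohort: raw morning/evening logs generated from a known
# bivariate VAR ground truth, so every downstream stage can be tested
# without access to clinical data.

#' Ground-truth parameters for one synthetic patient
#'
#' Defines the latent data-generating process for a simulated patient: a
#' stationary bivariate VAR(p) on (time in bed \[minutes\], depression
#' core-symptom score \[0-10\]), plus an optional per-day linear trend and a
#' missing-completely-at-random diary mechanism.
#'
#' Defaults describe a plausible outpatient: mean time in bed around
#' 480 min with innovation SD 45 min, mean depression score around 4 with
#' innovation SD 0.9, moderate day-to-day persistence (own-lag 0.3) and no
#' cross-coupling, trend or missingness.
#'
#' @param patient_id identifier string.
#' @param n_days number of consecutive diary days. Study-realistic
#'   collection periods span 143-205 days; values outside that range
#'   require `strict_days = FALSE`.
#' @param lag_order VAR order p >= 1.
#' @param intercepts length-2 intercept vector (minutes, score units).
#' @param coef_matrices list of p 2x2 lag-coefficient matrices; element
#'   `[i, j]` of matrix k is the effect of variable j at t-k on variable i
#'   (variable 1 = sleep, variable 2 = depression). The companion-matrix
#'   spectral radius must be < 1.
#' @param resid_cov 2x2 symmetric positive-definite innovation covariance.
#' @param trend_slopes length-2 per-day linear drift added on top of the
#'   stationary VAR.
#' @param missing_prob probability that a morning (resp. evening) log is
#'   skipped on any day; capped at 0.30, the study exclusion bound.
#' @param seed integer seed making the patient reproducible.
#' @param strict_days enforce the 143-205 day range.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(patient_id = "sim01",
                            n_days = 170L,
                            lag_order = 1L,
                            intercepts = c(336, 2.8),
                            coef_matrices = list(matrix(c(0.3, 0, 0, 0.3), 2, 2)),
                            resid_cov = diag(c(45^2, 0.9^2)),
                            trend_slopes = c(0, 0),
                            missing_prob = 0,
                            seed = 1L,
                            strict_days = TRUE) {
  n_days <- as.integer(n_days)
  lag_order <- as.integer(lag_order)
  stopifnot(lag_order >= 1L, length(intercepts) == 2L,
            length(trend_slopes) == 2L, length(coef_matrices) == lag_order)
  if (strict_days && (n_days < 143L || n_days > 205L)) {
    stop("n_days = ", n_days, " outside the default 143-205 day range; ",
         "pass strict_days = FALSE to override")
  }
  rho <- spectral_radius(coef_matrices)
  if (rho >= 1) {
    stop("coef_matrices define a non-stationary VAR: companion spectral ",
         "radius ", format(rho, digits = 4), " >= 1")
  }
  if (!isTRUE(all.equal(resid_cov, t(resid_cov)))) {
    stop("resid_cov must be symmetric")
  }
  ev <- eigen(resid_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("resid_cov must be positive definite")
  if (missing_prob < 0 || missing_prob > 0.30) {
    stop("missing_prob = ", missing_prob,
         " outside [0, 0.30]; series with more than 30% missing days are ",
         "excluded from analysis, so they are not generated")
  }
  structure(
    list(patient_id = patient_id, n_days = n_days, lag_order = lag_order,
         intercepts = as.numeric(intercepts), coef_matrices = coef_matrices,
         resid_cov = resid_cov, trend_slopes = as.numeric(trend_slopes),
         missing_prob = missing_prob, seed = as.integer(seed),
         spectral_radius = rho),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic patient ", x$patient_id, ": VAR(", x$lag_order, "), ",
      x$n_days, " days, missing_prob = ", x$missing_prob,
      ", spectral radius = ", format(x$spectral_radius, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Simulate the latent bivariate series of a synthetic patient
#'
#' Draws the continuous latent (sleep, depression) series from the truth's
#' VAR with Gaussian innovations, after a burn-in that removes dependence
#' on the starting values, then adds the linear trend. No clipping or
#' diary quantisation is applied, so the output obeys exact VAR theory
#' (used e.g. to check sample autocovariances against the Yule-Walker
#' solution).
#'
#' @param truth a [synthetic_truth()].
#' @param n_days optional override of `truth$n_days` (e.g. very long runs
#'   for distributional checks).
#' @param burn_in days discarded before the kept sample.
#' @return an `n_days` x 2 matrix with columns `sleep`, `dep`.
#' @export
simulate_latent <- function(truth, n_days = truth$n_days, burn_in = 200L) {
  p <- truth$lag_order
  n_tot <- n_days + burn_in
  L <- t(chol(truth$resid_cov))
  eps <- t(L %*% matrix(stats::rnorm(2L * n_tot), 2L, n_tot))
  mu <- solve(diag(2) - Reduce(`+`, truth$coef_matrices), truth$intercepts)
  y <- matrix(rep(mu, each = n_tot), n_tot, 2L)
  for (t in (p + 1L):n_tot) {
    acc <- truth$intercepts + eps[t, ]
    for (l in seq_len(p)) {
      acc <- acc + truth$coef_matrices[[l]] %*% y[t - l, ]
    }
    y[t, ] <- acc
  }
  y <- y[burn_in + seq_len(n_days), , drop = FALSE]
  y <- y + outer(seq_len(n_days) - 1, truth$trend_slopes)
  colnames(y) <- c("sleep", "dep")
  y
}

#' Generate raw diary logs for one synthetic patient
#'
#' Renders the latent series as the raw logs a diary app would export: a
#' morning log (go-to-bed and get-up clock times plus self-reported
#' minutes slept) and an evening log (two 0-10 depression items). The
#' latent sleep variable is time in bed; clock times are back-computed at
#' 1-minute resolution so that the time in bed derived from them equals
#' the (rounded) latent value. Total sleep time is time in bed minus a
#' uniform 10-45 min sleep-onset/wake latency. The two depression items
#' are placed symmetrically around the latent score (0.1 resolution) so
#' their mean recovers it. Morning and evening logs are dropped
#' independently with probability `missing_prob`.
#'
#' Values are clipped to the instruments' ranges after generation
#' (depression to \[0, 10\], time in bed to \[1, 1439\] minutes so the bed
#' interval stays a valid, non-zero clock span); the number of clipped
#' days is recorded in the `clipped` attribute. Default parameters keep
#' clipping negligible.
#'
#' @param truth a [synthetic_truth()].
#' @param start_date first diary date.
#' @param bed_window evening window (HH:MM pair, may wrap midnight) in
#'   which the go-to-bed time is placed uniformly; affects only the clock
#'   times, not the derived variables.
#' @return a `data.frame` of class `diary_log` with one row per day and
#'   columns `patient_id`, `date`, `go_to_bed`, `get_up`, `sleep_minutes`,
#'   `item_interest`, `item_mood`. Attributes: `latent` (the emitted
#'   per-day `tib_min`, `tst_min`, `dep_score` before any blanking),
#'   `clipped` (days clipped per variable), `truth`.
#' @export
generate_patient <- function(truth, start_date = as.Date("2023-01-01"),
                             bed_window = c("21:00", "00:30")) {
  if (!inherits(truth, "synthetic_truth")) {
    truth <- do.call(synthetic_truth, truth)
  }
  set.seed(truth$seed)
  n <- truth$n_days
  lat <- simulate_latent(truth)

  clip_sleep <- sum(lat[, 1L] < 1 | lat[, 1L] > 1439)
  clip_dep <- sum(lat[, 2L] < 0 | lat[, 2L] > 10)
  tib <- as.integer(round(pmin(pmax(lat[, 1L], 1), 1439)))
  dep <- pmin(pmax(lat[, 2L], 0), 10)

  # depression items: symmetric around the latent score at 0.1 resolution
  half_gap <- round(stats::runif(n, 0, pmin(dep, 10 - dep, 2)), 1)
  item_hi <- round(dep + half_gap, 1)
  item_lo <- round(dep - half_gap, 1)
  dep_emit <- (item_hi + item_lo) / 2
  swap <- stats::runif(n) < 0.5     # which item sits above the mean varies
  item_interest <- ifelse(swap, item_hi, item_lo)
  item_mood <- ifelse(swap, item_lo, item_hi)

  latency <- sample(10:45, n, replace = TRUE)
  tst <- pmax(tib - latency, 0L)

  win <- parse_clock(bed_window)
  span <- (win[2L] - win[1L]) %% 1440
  bed_min <- (win[1L] + sample.int(span + 1L, n, replace = TRUE) - 1L) %% 1440
  up_min <- (bed_min + tib) %% 1440

  miss_morning <- stats::runif(n) < truth$missing_prob
  miss_evening <- stats::runif(n) < truth$missing_prob

  logs <- data.frame(
    patient_id = truth$patient_id,
    date = start_date + seq_len(n) - 1L,
    go_to_bed = ifelse(miss_morning, NA_character_, format_clock(bed_min)),
    get_up = ifelse(miss_morning, NA_character_, format_clock(up_min)),
    sleep_minutes = ifelse(miss_morning, NA_integer_, tst),
    item_interest = ifelse(miss_evening, NA_real_, item_interest),
    item_mood = ifelse(miss_evening, NA_real_, item_mood),
    stringsAsFactors = FALSE)
  class(logs) <- c("diary_log", "data.frame")
  attr(logs, "latent") <- data.frame(
    date = logs$date, tib_min = tib, tst_min = tst, dep_score = dep_emit)
  attr(logs, "clipped") <- c(sleep = clip_sleep, dep = clip_dep)
  attr(logs, "truth") <- truth
  logs
}

#' Default sampling ranges for a synthetic cohort
#'
#' Per-patient ground-truth parameters are drawn uniformly from these
#' ranges. Day counts span the study-realistic 143-205; own-lag
#' persistence, innovation scales and means are set so that generated
#' diaries stay well inside the instrument bounds (negligible clipping).
#'
#' @return named list of ranges understood by [generate_cohort()].
#' @export
cohort_ranges <- function() {
  list(n_days = c(143L, 205L),
       own_coef = c(0.15, 0.45),
       sleep_mean = c(430, 540),
       dep_mean = c(2.5, 5.5),
       sleep_sd = c(35, 55),       # innovation SD, minutes
       dep_sd = c(0.7, 1.1),       # innovation SD, score units
       resid_corr = c(-0.15, 0.15),
       trend_sleep = c(0, 0),
       trend_dep = c(0, 0),
       missing_prob = c(0, 0))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-patient truths independently from `ranges`, optionally
#' coupling a subset of patients with a lag-1 cross effect of given
#' standardized strength, and renders each patient's raw diary logs.
#' Truths are returned alongside the data so parameter-recovery and
#' power properties can be tested end to end.
#'
#' The standardized coupling strength `cross_coef_std` is the lag-1
#' coefficient the cross effect would have if both series were scaled to
#' unit innovation SD; it is converted to raw units through the drawn
#' innovation SDs, so a value of 0.3 means "a 1-SD day moves tomorrow's
#' other variable by 0.3 of its SD" regardless of the minutes/score scales.
#'
#' @param n_patients number of patients (>= 1).
#' @param ranges sampling ranges, see [cohort_ranges()].
#' @param n_coupled how many patients (the first `n_coupled`) carry a true
#'   cross effect.
#' @param cross_coef_std standardized lag-1 cross coefficient for coupled
#'   patients.
#' @param coupling direction of the true effect for coupled patients.
#' @param seed cohort-level seed; per-patient seeds are derived from it.
#' @param max_attempts resampling attempts per patient before giving up
#'   when a draw is non-stationary.
#' @return list with `logs` (list of `diary_log`) and `truths` (list of
#'   [synthetic_truth()]).
#' @export
generate_cohort <- function(n_patients, ranges = cohort_ranges(),
                            n_coupled = 0L, cross_coef_std = 0.3,
                            coupling = c("sleep_to_dep", "dep_to_sleep"),
                            seed = 1L, max_attempts = 50L) {
  stopifnot(n_patients >= 1L, n_coupled <= n_patients)
  coupling <- match.arg(coupling)
  set.seed(seed)
  runif_r <- function(r) stats::runif(1, r[1L], r[2L])
  truths <- vector("list", n_patients)
  logs <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    truth <- NULL
    for (att in seq_len(max_attempts)) {
      own <- c(runif_r(ranges$own_coef), runif_r(ranges$own_coef))
      sds <- c(runif_r(ranges$sleep_sd), runif_r(ranges$dep_sd))
      A <- diag(own)
      if (i <= n_coupled) {
        if (coupling == "sleep_to_dep") {
          A[2L, 1L] <- cross_coef_std * sds[2L] / sds[1L]
        } else {
          A[1L, 2L] <- cross_coef_std * sds[1L] / sds[2L]
        }
      }
      if (spectral_radius(list(A)) >= 1) next
      rho <- runif_r(ranges$resid_corr)
      Sig <- diag(sds^2)
      Sig[1L, 2L] <- Sig[2L, 1L] <- rho * sds[1L] * sds[2L]
      mu <- c(runif_r(ranges$sleep_mean), runif_r(ranges$dep_mean))
      truth <- try(synthetic_truth(
        patient_id = sprintf("sim%02d", i),
        n_days = sample(seq(ranges$n_days[1L], ranges$n_days[2L]), 1L),
        lag_order = 1L,
        intercepts = as.numeric((diag(2) - A) %*% mu),
        coef_matrices = list(A),
        resid_cov = Sig,
        trend_slopes = c(runif_r(ranges$trend_sleep),
                         runif_r(ranges$trend_dep)),
        missing_prob = runif_r(ranges$missing_prob),
        seed = sample.int(.Machine$integer.max, 1L)),
        silent = TRUE)
      if (!inherits(truth, "try-error")) break
      truth <- NULL
    }
    if (is.null(truth)) {
      stop("could not draw a stationary truth for patient ", i,
           " within ", max_attempts, " attempts")
    }
    truths[[i]] <- truth
    logs[[i]] <- generate_patient(truth)
  }
  list(logs = logs, truths = truths)
}

#' Write diary logs to CSV
#'
#' One row per patient-day with ISO-8601 dates and empty cells for
#' missing fields; several patients' logs may be concatenated.
#'
#' @param logs a `diary_log` data frame or a list of them.
#' @param path output CSV path.
#' @export
write_diary <- function(logs, path) {
  if (is.data.frame(logs)) logs <- list(logs)
  all <- do.call(rbind, lapply(logs, function(x) {
    x <- as.data.frame(x)
    x$date <- format(x$date, "%Y-%m-%d")
    x
  }))
  utils::write.csv(all, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read diary logs from CSV
#'
#' @param path CSV written by [write_diary()] (or any file in the same
#'   dialect).
#' @return a `diary_log` data frame (possibly several patients).
#' @export
read_diary <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character",
                                      go_to_bed = "character",
                                      get_up = "character"))
  need <- c("patient_id", "date", "go_to_bed", "get_up", "sleep_minutes",
            "item_interest", "item_mood")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("diary CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  x$date <- as.Date(x$date)
  x$go_to_bed[!is.na(x$go_to_bed) & x$go_to_bed == ""] <- NA_character_
  x$get_up[!is.na(x$get_up) & x$get_up == ""] <- NA_character_
  class(x) <- c("diary_log", "data.frame")
  x
}

#' Serialize ground truths to a YAML sidecar
#'
#' @param truths list of [synthetic_truth()] objects.
#' @param path output YAML path.
#' @export
write_truths <- function(truths, path) {
  if (inherits(truths, "synthetic_truth")) truths <- list(truths)
  ser <- lapply(truths, function(tr) {
    list(patient_id = tr$patient_id, n_days = tr$n_days,
         lag_order = tr$lag_order, intercepts = tr$intercepts,
         coef_matrices = lapply(tr$coef_matrices, function(m) {
           lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
         }),
         resid_cov = lapply(seq_len(nrow(tr$resid_cov)),
                            function(i) as.numeric(tr$resid_cov[i, ])),
         trend_slopes = tr$trend_slopes, missing_prob = tr$missing_prob,
         seed = tr$seed)
  })
  writeLines(yaml::as.yaml(ser), path)
  invisible(path)
}
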