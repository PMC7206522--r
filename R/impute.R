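# Kalman-smoothing imputation: missing diary days are replaced by the
# smoothed state expectation of a univariate ARIMA state-space model
# selected on the observed series itself. Strictly univariate by design:
# the other series of the pair is never consulted, so no spurious
# cross-correlation is introduced by the imputation step.

#' Impute missing values by Kalman smoothing of an ARIMA model
#'
#' Model selection: the differencing order `d` is chosen by the KPSS test
#' (on a linearly interpolated copy, used for order choice only); the AR
#' and MA orders are then chosen on a small grid (AR 0..3, MA 0..1) by
#' AIC, each candidate fitted by maximum likelihood on the series with
#' its gaps (the Kalman filter handles missing observations in the
#' likelihood). With `d = 1` a drift regressor is included so trending
#' series continue their drift through gaps. The selected model is cast
#' to state-space form and the fixed-interval Kalman smoother supplies
#' the conditional expectation at every missing position; observed
#' values are never altered.
#'
#' Degenerate inputs: an (almost) exactly linear series makes the ARIMA
#' innovation variance collapse, so it is imputed from its least-squares
#' line directly; a flat series is filled with its constant value, with
#' a warning.
#'
#' @param x numeric series with `NA` gaps; at least 30 observed values.
#' @param max_ar,max_ma,max_d grid bounds for model selection.
#' @param alpha level of the KPSS test used for the `d` choice.
#' @param variable series name for messages and the report.
#' @return list of class `imputation`: `values` (complete series) and
#'   `report` — a list with `variable`, `order` (p, d, q), `drift`,
#'   `aic`, `positions` (the imputed indices) and `imputed` (their
#'   values).
#' @export
kalman_impute <- function(x, max_ar = 3L, max_ma = 1L, max_d = 1L,
                          alpha = 0.05, variable = "series") {
  x <- as.numeric(x)
  n <- length(x)
  miss <- which(is.na(x))
  obs <- which(!is.na(x))
  if (length(obs) == 0L) stop("series '", variable, "' is entirely missing")
  if (length(obs) < 30L) {
    stop("series '", variable, "' has only ", length(obs),
         " observed values; at least 30 are required to select an ",
         "imputation model")
  }
  report <- list(variable = variable, order = c(0L, 0L, 0L), drift = FALSE,
                 aic = NA_real_, positions = miss, imputed = numeric(0))
  if (length(miss) == 0L) {
    return(structure(list(values = x, report = report),
                     class = "imputation"))
  }

  if (stats::sd(x[obs]) < .Machine$double.eps^0.5) {
    warning("series '", variable,
            "' has zero variance; missing values filled with the constant")
    x[miss] <- x[obs][1L]
    report$imputed <- x[miss]
    report$method <- "constant"
    return(structure(list(values = x, report = report),
                     class = "imputation"))
  }

  # (near-)deterministic linear series: the smoother degenerates, the
  # least-squares line is the exact answer
  linfit <- stats::lm.fit(cbind(1, obs), x[obs])
  if (stats::sd(linfit$residuals) <
      1e-8 * (stats::sd(x[obs]) + abs(mean(x[obs])))) {
    x[miss] <- linfit$coefficients[1L] + linfit$coefficients[2L] * miss
    report$imputed <- x[miss]
    report$method <- "deterministic_line"
    report$order <- c(0L, 1L, 0L)
    report$drift <- TRUE
    return(structure(list(values = x, report = report),
                     class = "imputation"))
  }

  # differencing order from KPSS on an interpolated copy (order choice only)
  xi <- stats::approx(obs, x[obs], xout = seq_len(n), rule = 2)$y
  d <- max_d
  for (dd in 0:max_d) {
    y <- if (dd == 0L) xi else diff(xi, differences = dd)
    if (stats::sd(y) < .Machine$double.eps^0.5 ||
        kpss_test(y)$p_value >= alpha) {
      d <- dd
      break
    }
  }

  xreg <- if (d > 0L) {
    matrix(seq_len(n), ncol = 1L, dimnames = list(NULL, "drift"))
  }
  best <- NULL
  best_aic <- Inf
  best_order <- NULL
  for (p in 0:max_ar) {
    for (q in 0:max_ma) {
      fit <- tryCatch(
        suppressWarnings(stats::arima(x, order = c(p, d, q), xreg = xreg,
                                      method = "ML")),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$aic) && fit$aic < best_aic) {
        best <- fit
        best_aic <- fit$aic
        best_order <- c(p, d, q)
      }
    }
  }
  if (is.null(best)) {
    warning("no ARIMA candidate converged for '", variable,
            "'; falling back to linear interpolation")
    x[miss] <- xi[miss]
    report$imputed <- x[miss]
    report$method <- "interpolation"
    return(structure(list(values = x, report = report),
                     class = "imputation"))
  }

  # regression part handled outside the state space: subtract it, smooth,
  # add it back
  cf <- stats::coef(best)
  cont <- numeric(n)
  if ("intercept" %in% names(cf)) cont <- cont + cf[["intercept"]]
  if ("drift" %in% names(cf)) cont <- cont + cf[["drift"]] * seq_len(n)
  ks <- stats::KalmanSmooth(x - cont, best$model, nit = -1L)
  pred <- drop(ks$smooth %*% as.matrix(best$model$Z)) + cont
  x[miss] <- pred[miss]

  report$order <- best_order
  report$drift <- d > 0L
  report$aic <- best_aic
  report$imputed <- x[miss]
  report$method <- "kalman_smoother"
  structure(list(values = x, report = report), class = "imputation")
}

#' @export
print.imputation <- function(x, ...) {
  r <- x$report
  cat("Kalman imputation for '", r$variable, "': ", length(r$positions),
      " value(s) imputed", sep = "")
  if (!is.null(r$method)) cat(" [", r$method, "]", sep = "")
  cat(", ARIMA(", paste(r$order, collapse = ","), ")",
      if (isTRUE(r$drift)) " + drift", "\n", sep = "")
  invisible(x)
}

#' Serialize imputation / filter reports to YAML
#'
#' @param reports a named list of imputation reports and/or filter specs
#'   for one patient.
#' @param path output YAML path.
#' @export
write_reports <- function(reports, path) {
  strip <- function(z) {
    if (is.list(z)) lapply(z, strip) else if (is.function(z)) NULL else z
  }
  writeLines(yaml::as.yaml(strip(reports)), path)
  invisible(path)
}
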