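# Unit-root / stationarity testing and the ARIMA-style linear filter that
# brings each daily series to stationarity before VAR fitting.
#
# ADF and KPSS are implemented here directly (standard auxiliary
# regressions; p-values interpolated in the published Dickey-Fuller and
# KPSS critical-value tables, clamped at the table edges).

#' Augmented Dickey-Fuller test
#'
#' Tests the null of a unit root against stationarity around a constant
#' and linear trend. The auxiliary regression is
#' `diff(x)[t] ~ 1 + t + x[t-1] + diff(x)[t-1..k]`; the statistic is the
#' t-ratio on `x[t-1]`, with p-value interpolated in the Dickey-Fuller
#' distribution for the trend case. Small p-values reject the unit root.
#'
#' @param x numeric series, no missing values.
#' @param k number of lagged differences (default `trunc((n-1)^(1/3))`).
#' @return list with `statistic`, `p_value`, `k`.
#' @export
adf_test <- function(x, k = trunc((length(x) - 1)^(1/3))) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("adf_test requires a complete series")
  n <- length(x)
  if (n < k + 10L) stop("series too short for ADF with k = ", k)
  dx <- diff(x)
  m <- length(dx)
  yt <- dx[(k + 1L):m]
  xlag <- x[(k + 1L):m]
  tt <- (k + 1L):m
  X <- cbind(1, tt, xlag)
  if (k > 0L) {
    for (j in seq_len(k)) X <- cbind(X, dx[(k + 1L - j):(m - j)])
  }
  fit <- stats::lm.fit(X, yt)
  res <- fit$residuals
  df <- length(yt) - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  stat <- fit$coefficients[3L] / sqrt(s2 * XtXinv[3L, 3L])

  # Dickey-Fuller critical values, trend case (rows: p-levels, cols: n)
  tbl <- -1 * matrix(c(4.38, 4.15, 4.04, 3.99, 3.98, 3.96,
                       3.95, 3.80, 3.73, 3.69, 3.68, 3.66,
                       3.60, 3.50, 3.45, 3.43, 3.42, 3.41,
                       3.24, 3.18, 3.15, 3.13, 3.13, 3.12,
                       1.14, 1.19, 1.22, 1.23, 1.24, 1.25,
                       0.80, 0.87, 0.90, 0.92, 0.93, 0.94,
                       0.50, 0.58, 0.62, 0.64, 0.65, 0.66,
                       0.15, 0.24, 0.28, 0.31, 0.32, 0.33),
                     8L, 6L, byrow = TRUE)
  tbl_n <- c(25, 50, 100, 250, 500, 1e5)
  tbl_p <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  crit <- apply(tbl, 1L, function(row) {
    stats::approx(tbl_n, row, xout = n, rule = 2)$y
  })
  p <- stats::approx(crit, tbl_p, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = p, k = k)
}

#' KPSS stationarity test
#'
#' Tests the null of stationarity (around a level or a linear trend)
#' against a unit root. Small p-values reject stationarity. Long-run
#' variance uses a Bartlett window with the short truncation lag
#' `trunc(3 * sqrt(n) / 13)`.
#'
#' @param x numeric series, no missing values.
#' @param null `"level"` (default) or `"trend"` stationarity.
#' @return list with `statistic`, `p_value`, `lags`.
#' @export
kpss_test <- function(x, null = c("level", "trend")) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("kpss_test requires a complete series")
  null <- match.arg(null)
  n <- length(x)
  if (n < 12L) stop("series too short for KPSS")
  if (null == "level") {
    e <- x - mean(x)
    crit <- c(0.347, 0.463, 0.574, 0.739)
  } else {
    tt <- seq_len(n)
    e <- stats::lm.fit(cbind(1, tt), x)$residuals
    crit <- c(0.119, 0.146, 0.176, 0.216)
  }
  S <- cumsum(e)
  l <- trunc(3 * sqrt(n) / 13)
  s2 <- sum(e^2) / n
  if (l > 0L) {
    for (i in seq_len(l)) {
      w <- 1 - i / (l + 1)
      s2 <- s2 + 2 * w * sum(e[(i + 1L):n] * e[seq_len(n - i)]) / n
    }
  }
  stat <- sum(S^2) / (n^2 * s2)
  p <- stats::approx(crit, c(0.10, 0.05, 0.025, 0.01), xout = stat,
                     rule = 2)$y
  list(statistic = unname(stat), p_value = p, lags = l)
}

#' Difference a series to stationarity
#'
#' The linear filter of the analysis pipeline: the series is differenced
#' `d` times, with `d` the smallest order in `0..max_d` at which the
#' ADF/KPSS test pair agrees on stationarity at level `alpha` (ADF
#' rejects its unit-root null AND KPSS fails to reject its stationarity
#' null). An optional ordinary-least-squares linear detrend can be
#' applied before differencing.
#'
#' @param x complete numeric series (impute first).
#' @param max_d maximum differencing order (default 2).
#' @param alpha level for both stationarity tests (default 0.05).
#' @param detrend remove an OLS linear trend before testing/differencing.
#' @param variable series name used in messages and the returned spec.
#' @return list of class `filter_spec_result`: `values` (filtered series,
#'   shorter by `d`) and `spec` — a list with `variable`, `d`, `detrend`
#'   and the per-order test results (`tests`).
#' @export
stationarity_filter <- function(x, max_d = 2L, alpha = 0.05,
                                detrend = FALSE, variable = "series") {
  x <- as.numeric(x)
  if (anyNA(x)) stop("stationarity_filter requires a complete series: ",
                     variable)
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    stop("series '", variable, "' is constant: no variance to model")
  }
  if (detrend) {
    tt <- seq_along(x)
    x <- stats::lm.fit(cbind(1, tt), x)$residuals
  }
  tests <- list()
  for (d in 0:max_d) {
    y <- if (d == 0L) x else diff(x, differences = d)
    if (stats::sd(y) < .Machine$double.eps^0.5) {
      # differencing removed all variation (e.g. noiseless ramp): stationary
      tests[[paste0("d", d)]] <- list(adf = NA, kpss = NA, degenerate = TRUE)
      spec <- list(variable = variable, d = d, detrend = detrend,
                   tests = tests)
      return(structure(list(values = y, spec = spec),
                       class = "filter_spec_result"))
    }
    adf <- adf_test(y)
    kp <- kpss_test(y)
    tests[[paste0("d", d)]] <- list(adf = adf, kpss = kp)
    if (adf$p_value < alpha && kp$p_value >= alpha) {
      spec <- list(variable = variable, d = d, detrend = detrend,
                   tests = tests)
      return(structure(list(values = y, spec = spec),
                       class = "filter_spec_result"))
    }
  }
  stop("series '", variable, "' still non-stationary after differencing ",
       max_d, " times")
}

#' Impute and filter a bivariate pair for VAR fitting
#'
#' Runs each series through [kalman_impute()] (if it has missing values)
#' and [stationarity_filter()] independently, then aligns the pair on a
#' common time index: each series keeps its own differencing order, and
#' leading observations are trimmed so both filtered series start at the
#' index implied by the larger order of the pair.
#'
#' @param x,y the two daily series (may contain missing values).
#' @param var_names length-2 names, in the order (x, y).
#' @param ... passed on to [stationarity_filter()].
#' @return list with `y` (n x 2 matrix of aligned filtered series),
#'   `filters` (both filter specs), `imputations` (both imputation
#'   reports, `NULL` where nothing was missing).
#' @export
prepare_pair <- function(x, y, var_names = c("x", "y"), ...) {
  imp <- list(NULL, NULL)
  series <- list(as.numeric(x), as.numeric(y))
  for (i in 1:2) {
    if (anyNA(series[[i]])) {
      k <- kalman_impute(series[[i]], variable = var_names[i])
      series[[i]] <- k$values
      imp[[i]] <- k$report
    }
  }
  f1 <- stationarity_filter(series[[1L]], variable = var_names[1L], ...)
  f2 <- stationarity_filter(series[[2L]], variable = var_names[2L], ...)
  dmax <- max(f1$spec$d, f2$spec$d)
  trim <- function(f) {
    v <- f$values
    drop <- dmax - f$spec$d
    if (drop > 0L) v <- v[-seq_len(drop)]
    v
  }
  m <- cbind(trim(f1), trim(f2))
  colnames(m) <- var_names
  names(imp) <- var_names
  list(y = m, filters = list(f1$spec, f2$spec), imputations = imp)
}
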