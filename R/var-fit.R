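# Bivariate VAR(p) by equationwise ordinary least squares, with AIC lag
# selection, stability diagnostics and Granger causality testing. This is
# the core model of the package: one fit per patient and model
# (sleep variable, depression score).

# Design matrix of a VAR(p): response rows (p+1)..n, regressors an
# intercept and lags 1..p of both variables (blocked by lag).
var_design <- function(Y, p) {
  n <- nrow(Y)
  k <- ncol(Y)
  resp <- Y[(p + 1L):n, , drop = FALSE]
  X <- matrix(1, n - p, 1L + k * p)
  cn <- "const"
  for (l in seq_len(p)) {
    X[, 1L + (l - 1L) * k + seq_len(k)] <- Y[(p + 1L - l):(n - l), ]
    cn <- c(cn, paste0(colnames(Y), ".l", l))
  }
  colnames(X) <- cn
  list(y = resp, X = X)
}

#' Fit a bivariate vector autoregression to a patient's daily series
#'
#' Each of the two equations regresses the current value on an intercept
#' and lags `1..p` of both variables, estimated by ordinary least
#' squares. The innovation covariance is formed from the OLS residuals
#' with denominator `n_effective = n - p` (the maximum-likelihood
#' denominator), the Gaussian log-likelihood and AIC follow from it. If
#' `p` is not given it is selected by [select_lag()].
#'
#' @param y an n x 2 numeric matrix (or data frame) of aligned,
#'   complete, stationary series; column names become the variable
#'   names.
#' @param p lag order, >= 1; `NULL` (default) selects it by AIC.
#' @param max_lag largest candidate order for selection (default 7
#'   days).
#' @return an object of class `idiovar`: a list with `var_names`, `p`,
#'   `intercepts`, `coef_matrices` (list of p 2x2 matrices, element
#'   `[i, j]` of matrix k = coefficient of variable j at t-k in the
#'   equation for variable i), `resid_cov`, `coef_table` (per-equation
#'   estimates, standard errors, t and p values), `n_effective`,
#'   `log_lik`, `aic`, `fitted`, `residuals`, `y`.
#' @examples
#' y <- simulate_latent(synthetic_truth(seed = 7))
#' fit <- idiovar(y, p = 1)
#' fit
#' @export
idiovar <- function(y, p = NULL, max_lag = 7L) {
  Y <- as.matrix(y)
  if (ncol(Y) != 2L) stop("idiovar expects exactly two series")
  if (anyNA(Y)) stop("series must be complete; impute first")
  if (is.null(colnames(Y))) colnames(Y) <- c("y1", "y2")
  storage.mode(Y) <- "double"
  if (is.null(p)) p <- select_lag(Y, max_lag = max_lag)
  p <- as.integer(p)
  stopifnot(p >= 1L)
  n <- nrow(Y)
  if (n <= 2L * (2L * p + 1L)) {
    stop("series too short (", n, " points) to estimate a VAR(", p, ")")
  }
  d <- var_design(Y, p)
  qrX <- qr(d$X)
  if (qrX$rank < ncol(d$X)) {
    sds <- apply(Y, 2L, stats::sd)
    offender <- colnames(Y)[which.min(sds)]
    stop("regressor matrix is rank deficient (variable '", offender,
         "' is (near-)constant?)")
  }
  B <- qr.coef(qrX, d$y)                  # (1 + 2p) x 2
  U <- d$y - d$X %*% B
  n_eff <- n - p
  Sigma <- crossprod(U) / n_eff
  dimnames(Sigma) <- list(colnames(Y), colnames(Y))

  # per-equation inference (classical OLS standard errors)
  XtXinv <- chol2inv(qr.R(qrX))
  df_res <- n_eff - ncol(d$X)
  coef_table <- lapply(1:2, function(i) {
    se <- sqrt(diag(XtXinv) * sum(U[, i]^2) / df_res)
    est <- B[, i]
    tv <- est / se
    data.frame(term = rownames(B), estimate = est, std_error = se,
               t_value = tv,
               p_value = 2 * stats::pt(-abs(tv), df_res),
               row.names = NULL)
  })
  names(coef_table) <- colnames(Y)

  A <- lapply(seq_len(p), function(l) {
    m <- t(B[1L + (l - 1L) * 2L + 1:2, , drop = FALSE])
    dimnames(m) <- list(colnames(Y), colnames(Y))
    m
  })
  ll <- -n_eff / 2 * (2 * log(2 * pi) + log(det(Sigma)) + 2)
  npar <- 2L * (2L * p + 1L) + 3L
  rownames(B) <- colnames(d$X)

  structure(list(var_names = colnames(Y), p = p,
                 intercepts = unname(B[1L, ]), coef_matrices = A,
                 resid_cov = Sigma, coef_table = coef_table,
                 n_effective = n_eff, log_lik = ll,
                 aic = -2 * ll + 2 * npar, B = B,
                 fitted = d$X %*% B, residuals = U, y = Y,
                 call = match.call()),
            class = "idiovar")
}

#' Select the VAR lag order by AIC
#'
#' Fits all candidate orders `1..max_lag` on the common sample trimmed
#' to `max_lag` presample values, so the information criteria compare
#' like with like, and returns the AIC-minimising order (smallest order
#' on ties).
#'
#' @param y n x 2 matrix of aligned stationary series.
#' @param max_lag largest candidate (default 7 days).
#' @return the selected order `p`.
#' @export
select_lag <- function(y, max_lag = 7L) {
  Y <- as.matrix(y)
  n <- nrow(Y)
  max_lag <- as.integer(max_lag)
  if (n < 3L * max_lag) {
    stop("series of length ", n, " too short for lag selection up to ",
         max_lag)
  }
  if (n <= 10L * max_lag) {
    warning("series length ", n, " below the recommended 10 * max_lag = ",
            10L * max_lag, "; lag selection may be unstable")
  }
  if (is.null(colnames(Y))) colnames(Y) <- c("y1", "y2")
  aics <- vapply(seq_len(max_lag), function(p) {
    # common response sample: rows (max_lag+1)..n for every candidate
    d <- var_design(Y, p)
    keep <- (max_lag - p + 1L):nrow(d$X)
    X <- d$X[keep, , drop = FALSE]
    yy <- d$y[keep, , drop = FALSE]
    B <- qr.coef(qr(X), yy)
    U <- yy - X %*% B
    ne <- nrow(yy)
    Sigma <- crossprod(U) / ne
    ll <- -ne / 2 * (2 * log(2 * pi) + log(det(Sigma)) + 2)
    -2 * ll + 2 * (2 * (2 * p + 1) + 3)
  }, numeric(1))
  which.min(aics)
}

#' Companion-matrix stability check
#'
#' @param fit an `idiovar` fit, or a list of lag-coefficient matrices.
#' @return list with `spectral_radius` and logical `stable`
#'   (radius < 1).
#' @export
check_stability <- function(fit) {
  A <- if (inherits(fit, "idiovar")) fit$coef_matrices else fit
  rho <- spectral_radius(A)
  list(spectral_radius = rho, stable = rho < 1)
}

#' Granger causality test within a fitted VAR
#'
#' F-test of the null that all lag coefficients of `cause` in the
#' equation for `effect` are zero: the restricted equation (own lags
#' only) is refitted on the same sample, and
#' `F = ((RSS_r - RSS_u)/p) / (RSS_u/(n_eff - 2p - 1))` with p and
#' `n_eff - 2p - 1` degrees of freedom. No multiple-testing correction
#' is applied. The association sign is read off the cumulative
#' orthogonalized impulse response of `effect` to a shock in `cause` at
#' the 10-day horizon, i.e. "more cause is followed by more (positive)
#' or less (negative) effect overall".
#'
#' @param fit an `idiovar` fit.
#' @param cause,effect variable names (must differ).
#' @param alpha significance level (default 0.05).
#' @param horizon horizon of the cumulative impulse response that
#'   defines the sign (default 10 days).
#' @return object of class `granger_test`: `cause`, `effect`,
#'   `statistic`, `df1`, `df2`, `p_value`, `significant`,
#'   `association_sign` (`"positive"`/`"negative"`), `alpha`.
#' @export
granger_test <- function(fit, cause, effect, alpha = 0.05, horizon = 10L) {
  stopifnot(inherits(fit, "idiovar"))
  vn <- fit$var_names
  if (!cause %in% vn || !effect %in% vn || cause == effect) {
    stop("cause and effect must be distinct variables of the fit: ",
         paste(vn, collapse = ", "))
  }
  ie <- match(effect, vn)
  ic <- match(cause, vn)
  p <- fit$p
  n_eff <- fit$n_effective

  rss_u <- sum(fit$residuals[, ie]^2)
  d <- var_design(fit$y, p)
  own_cols <- c(1L, 1L + (seq_len(p) - 1L) * 2L + ie)
  Xr <- d$X[, own_cols, drop = FALSE]
  rr <- stats::lm.fit(Xr, d$y[, ie])
  rss_r <- sum(rr$residuals^2)
  if (rss_r < rss_u - 1e-8 * (rss_u + 1)) {
    stop("internal error: restricted RSS below unrestricted RSS")
  }
  df2 <- n_eff - (2L * p + 1L)
  stat <- ((rss_r - rss_u) / p) / (rss_u / df2)
  pval <- stats::pf(stat, p, df2, lower.tail = FALSE)

  cum <- irf(fit, impulse = cause, response = effect,
             H = horizon)$cumulative
  sign_h <- cum[length(cum)]

  structure(list(cause = cause, effect = effect, statistic = stat,
                 df1 = p, df2 = df2, p_value = pval,
                 significant = pval < alpha,
                 association_sign = if (sign_h >= 0) "positive" else "negative",
                 cumulative_irf = sign_h, alpha = alpha),
            class = "granger_test")
}

#' @export
print.granger_test <- function(x, ...) {
  cat(sprintf("Granger causality %s -> %s: F(%d, %d) = %.3f, p = %.4f %s\n",
              x$cause, x$effect, x$df1, x$df2, x$statistic, x$p_value,
              if (x$significant) {
                paste0("[significant at ", x$alpha, ", ",
                       x$association_sign, " association]")
              } else "[not significant]"))
  invisible(x)
}

# ---- methods on idiovar ----------------------------------------------------

#' @export
print.idiovar <- function(x, ...) {
  st <- check_stability(x)
  cat("Bivariate VAR(", x$p, ") on (", paste(x$var_names, collapse = ", "),
      "), ", x$n_effective, " effective observations\n", sep = "")
  cat("AIC ", format(x$aic, digits = 6), "; companion spectral radius ",
      format(st$spectral_radius, digits = 3),
      if (st$stable) " (stable)" else " (UNSTABLE)", "\n", sep = "")
  for (l in seq_len(x$p)) {
    cat("A", l, ":\n", sep = "")
    print(round(x$coef_matrices[[l]], 4))
  }
  invisible(x)
}

#' @export
summary.idiovar <- function(object, ...) {
  structure(list(fit = object, stability = check_stability(object)),
            class = "summary.idiovar")
}

#' @export
print.summary.idiovar <- function(x, ...) {
  print(x$fit)
  cat("\nResidual covariance:\n")
  print(round(x$fit$resid_cov, 4))
  for (v in x$fit$var_names) {
    cat("\nEquation for ", v, ":\n", sep = "")
    tab <- x$fit$coef_table[[v]]
    tab[-1L] <- lapply(tab[-1L], round, 4)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.idiovar <- function(object, ...) object$B

#' @export
residuals.idiovar <- function(object, ...) object$residuals

#' @export
fitted.idiovar <- function(object, ...) object$fitted

#' @export
logLik.idiovar <- function(object, ...) {
  structure(object$log_lik, df = 2 * (2 * object$p + 1) + 3,
            nobs = object$n_effective, class = "logLik")
}

#' Iterated point forecasts from a fitted VAR
#'
#' @param object an `idiovar` fit.
#' @param n_ahead forecast horizon in days.
#' @param ... unused.
#' @return `n_ahead` x 2 matrix of forecasts.
#' @export
predict.idiovar <- function(object, n_ahead = 10L, ...) {
  p <- object$p
  hist <- object$y[nrow(object$y) - (p:1) + 1L, , drop = FALSE]
  out <- matrix(NA_real_, n_ahead, 2L,
                dimnames = list(NULL, object$var_names))
  buf <- rbind(hist, out)
  for (h in seq_len(n_ahead)) {
    acc <- object$intercepts
    for (l in seq_len(p)) {
      acc <- acc + object$coef_matrices[[l]] %*% buf[p + h - l, ]
    }
    buf[p + h, ] <- acc
  }
  buf[p + seq_len(n_ahead), , drop = FALSE]
}

#' Simulate new series from a fitted VAR
#'
#' Draws Gaussian innovations from the estimated residual covariance and
#' iterates the fitted difference equation, after a burn-in started at
#' the process mean.
#'
#' @param object an `idiovar` fit.
#' @param nsim number of series to simulate.
#' @param seed optional seed.
#' @param n length of each simulated series (defaults to the fitted
#'   sample length).
#' @param burn_in presample days discarded.
#' @param ... unused.
#' @return a list of n x 2 matrices (a single matrix if `nsim = 1`).
#' @export
simulate.idiovar <- function(object, nsim = 1L, seed = NULL,
                             n = nrow(object$y), burn_in = 100L, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$p
  L <- t(chol(object$resid_cov))
  one <- function() {
    n_tot <- n + burn_in
    eps <- t(L %*% matrix(stats::rnorm(2L * n_tot), 2L, n_tot))
    mu <- tryCatch(
      solve(diag(2) - Reduce(`+`, object$coef_matrices),
            object$intercepts),
      error = function(e) colMeans(object$y))
    Y <- matrix(rep(mu, each = n_tot), n_tot, 2L)
    for (t in (p + 1L):n_tot) {
      acc <- object$intercepts + eps[t, ]
      for (l in seq_len(p)) {
        acc <- acc + object$coef_matrices[[l]] %*% Y[t - l, ]
      }
      Y[t, ] <- acc
    }
    Y <- Y[burn_in + seq_len(n), , drop = FALSE]
    colnames(Y) <- object$var_names
    Y
  }
  out <- lapply(seq_len(nsim), function(i) one())
  if (nsim == 1L) out[[1L]] else out
}

#' Plot observed and fitted series of a VAR fit
#'
#' @param x an `idiovar` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.idiovar <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  n <- nrow(x$y)
  for (i in 1:2) {
    graphics::plot(seq_len(n), x$y[, i], type = "l", col = "grey40",
                   xlab = "day", ylab = x$var_names[i], ...)
    graphics::lines((x$p + 1L):n, x$fitted[, i], col = "firebrick")
  }
  invisible(x)
}
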