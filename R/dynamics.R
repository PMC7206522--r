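# Impulse-response and forecast-error variance machinery: moving-average
# recursion, orthogonalized IRFs scaled to a 1-SD shock over a 10-day
# horizon, residual-bootstrap confidence bands, and FEVD.

#' Moving-average coefficient matrices of a VAR
#'
#' The MA(infinity) representation underlying impulse responses and
#' variance decompositions: `Phi_0 = I`,
#' `Phi_h = sum_{k=1..min(h,p)} Phi_{h-k} A_k`.
#'
#' @param fit an `idiovar` fit (or a list of lag matrices).
#' @param H highest horizon (default 10 days).
#' @return list of `H + 1` matrices `Phi_0 .. Phi_H`. If the fit is
#'   unstable a warning is attached (`attr(, "unstable")`).
#' @export
ma_coefficients <- function(fit, H = 10L) {
  A <- if (inherits(fit, "idiovar")) fit$coef_matrices else fit
  p <- length(A)
  k <- nrow(A[[1L]])
  Phi <- vector("list", H + 1L)
  Phi[[1L]] <- diag(k)
  for (h in seq_len(H)) {
    acc <- matrix(0, k, k)
    for (l in seq_len(min(h, p))) {
      acc <- acc + Phi[[h - l + 1L]] %*% A[[l]]
    }
    Phi[[h + 1L]] <- acc
  }
  st <- check_stability(A)
  if (!st$stable) {
    warning("unstable VAR (spectral radius ",
            format(st$spectral_radius, digits = 3),
            "): impulse responses may diverge")
    attr(Phi, "unstable") <- TRUE
  }
  Phi
}

# Cholesky factor of the residual covariance under a given variable
# ordering, mapped back to the original variable positions.
chol_factor <- function(Sigma, perm) {
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("residual covariance is not positive definite")
  Pp <- t(chol(Sigma[perm, perm, drop = FALSE]))
  P <- matrix(0, nrow(Sigma), ncol(Sigma))
  P[perm, perm] <- Pp
  dimnames(P) <- dimnames(Sigma)
  P
}

#' Orthogonalized impulse response function
#'
#' Response of one variable to a one-time shock in the other (or
#' itself), identified recursively through the Cholesky factor of the
#' residual covariance and scaled so that the horizon-0 movement of the
#' impulse variable equals one standard deviation of the (filtered)
#' impulse series — the shock unit of the analysis. `shock = "orthogonal"`
#' instead leaves the conventional one-orthogonal-innovation unit.
#'
#' @param fit an `idiovar` fit (must be stable for meaningful output).
#' @param impulse,response variable names.
#' @param H horizon in days (default 10).
#' @param shock `"series"` (1 SD of the impulse series, default) or
#'   `"orthogonal"` (1 orthogonalized innovation).
#' @param ordering Cholesky ordering as a character vector of the two
#'   variable names; default is the fit's column order (in the diary
#'   pipeline: sleep first, matching the convention that the night's
#'   sleep precedes the same-day evening rating).
#' @param boot compute percentile bootstrap bands ([irf_bands()]).
#' @param runs,level,seed bootstrap settings, see [irf_bands()].
#' @return object of class `idiovar_irf`: `horizons` (0..H), `point`,
#'   `cumulative`, `shock_sd`, `impulse`, `response`, `ordering`, and —
#'   with `boot = TRUE` — `lower`, `upper`, `cum_lower`, `cum_upper`,
#'   `level`, `completion_rate`.
#' @export
irf <- function(fit, impulse, response, H = 10L,
                shock = c("series", "orthogonal"), ordering = NULL,
                boot = FALSE, runs = 500L, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "idiovar"))
  shock <- match.arg(shock)
  vn <- fit$var_names
  if (is.null(ordering)) ordering <- vn
  perm <- match(ordering, vn)
  if (anyNA(perm) || length(perm) != 2L) {
    stop("ordering must be a permutation of: ", paste(vn, collapse = ", "))
  }
  j <- match(impulse, vn)
  i <- match(response, vn)
  if (is.na(j) || is.na(i)) stop("unknown impulse/response variable")

  P <- chol_factor(fit$resid_cov, perm)
  Phi <- ma_coefficients(fit, H)
  shock_sd <- if (shock == "series") stats::sd(fit$y[, j]) else P[j, j]
  scale <- shock_sd / P[j, j]
  point <- vapply(Phi, function(M) scale * (M %*% P)[i, j], numeric(1))

  out <- structure(
    list(impulse = impulse, response = response, horizons = 0:H,
         point = point, cumulative = cumsum(point), shock_sd = shock_sd,
         shock = shock, ordering = ordering),
    class = "idiovar_irf")
  if (boot) {
    b <- irf_bands(fit, impulse = impulse, response = response, H = H,
                   shock = shock, ordering = ordering, runs = runs,
                   level = level, seed = seed)
    out[names(b)] <- b
  }
  out
}

#' Residual-bootstrap confidence bands for an impulse response
#'
#' Fitted residuals are recentred and resampled with replacement, a
#' bootstrap series is rebuilt from the estimated coefficients (initial
#' `p` observations kept), the VAR is refitted at the same order and the
#' IRF recomputed; the band is the per-horizon percentile interval.
#' A horizon's effect is read as significant when its band excludes 0.
#' Unstable refits are dropped; if more than 10% are, a warning reports
#' the completion rate.
#'
#' @inheritParams irf
#' @param runs bootstrap replicates (default 500).
#' @param level band level (default 0.95).
#' @param seed optional seed for reproducible bands.
#' @return list with `lower`, `upper`, `cum_lower`, `cum_upper` (length
#'   H + 1), `level`, `runs`, `completion_rate`.
#' @export
irf_bands <- function(fit, impulse, response, H = 10L,
                      shock = c("series", "orthogonal"), ordering = NULL,
                      runs = 500L, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "idiovar"))
  shock <- match.arg(shock)
  if (!is.null(seed)) set.seed(seed)
  p <- fit$p
  n <- nrow(fit$y)
  U <- sweep(fit$residuals, 2L, colMeans(fit$residuals))
  m <- nrow(U)
  pts <- matrix(NA_real_, runs, H + 1L)
  kept <- 0L
  for (r in seq_len(runs)) {
    Ub <- U[sample.int(m, m, replace = TRUE), , drop = FALSE]
    Yb <- fit$y
    for (t in (p + 1L):n) {
      acc <- fit$intercepts + Ub[t - p, ]
      for (l in seq_len(p)) {
        acc <- acc + fit$coef_matrices[[l]] %*% Yb[t - l, ]
      }
      Yb[t, ] <- acc
    }
    fb <- tryCatch(idiovar(Yb, p = p), error = function(e) NULL)
    if (is.null(fb) || !check_stability(fb)$stable) next
    kept <- kept + 1L
    pts[kept, ] <- suppressWarnings(
      irf(fb, impulse = impulse, response = response, H = H, shock = shock,
          ordering = ordering)$point)
  }
  if (kept == 0L) stop("all bootstrap refits failed or were unstable")
  pts <- pts[seq_len(kept), , drop = FALSE]
  completion <- kept / runs
  if (completion < 0.9) {
    warning(sprintf(
      "only %.0f%% of bootstrap refits were stable; bands use %d of %d runs",
      100 * completion, kept, runs))
  }
  a <- (1 - level) / 2
  cums <- t(apply(pts, 1L, cumsum))
  list(lower = apply(pts, 2L, stats::quantile, probs = a),
       upper = apply(pts, 2L, stats::quantile, probs = 1 - a),
       cum_lower = apply(cums, 2L, stats::quantile, probs = a),
       cum_upper = apply(cums, 2L, stats::quantile, probs = 1 - a),
       level = level, runs = runs, completion_rate = completion)
}

#' @export
print.idiovar_irf <- function(x, digits = 3, ...) {
  cat("Orthogonalized IRF: shock of 1 SD (", format(x$shock_sd, digits = 4),
      if (x$shock == "series") ", series scale" else ", innovation scale",
      ") in ", x$impulse, " -> response of ", x$response, "\n", sep = "")
  tab <- data.frame(horizon = x$horizons, response = round(x$point, digits),
                    cumulative = round(x$cumulative, digits))
  if (!is.null(x$lower)) {
    tab$lower <- round(x$lower, digits)
    tab$upper <- round(x$upper, digits)
  }
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot an impulse response with its confidence band
#'
#' Solid line: point response per day; dashed lines: bootstrap band
#' (when present); dotted line: zero.
#'
#' @param x an `idiovar_irf`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.idiovar_irf <- function(x, ...) {
  ylim <- range(0, x$point, x$lower, x$upper, na.rm = TRUE)
  graphics::plot(x$horizons, x$point, type = "l", lwd = 2, ylim = ylim,
                 xlab = "days after shock",
                 ylab = paste("response of", x$response),
                 main = paste0("1-SD shock in ", x$impulse), ...)
  graphics::abline(h = 0, lty = 3)
  if (!is.null(x$lower)) {
    graphics::lines(x$horizons, x$lower, lty = 2)
    graphics::lines(x$horizons, x$upper, lty = 2)
  }
  invisible(x)
}

#' Sensitivity of cross-responses to the Cholesky ordering
#'
#' Recursive identification depends on the variable ordering when the
#' residuals are contemporaneously correlated. This helper recomputes
#' the cross-response under both orderings and reports the largest
#' absolute disagreement, so materially order-dependent conclusions can
#' be flagged.
#'
#' @inheritParams irf
#' @return list with `max_abs_difference` and the two responses.
#' @export
ordering_sensitivity <- function(fit, impulse, response, H = 10L,
                                 shock = c("series", "orthogonal")) {
  shock <- match.arg(shock)
  vn <- fit$var_names
  r1 <- irf(fit, impulse, response, H = H, shock = shock, ordering = vn)
  r2 <- irf(fit, impulse, response, H = H, shock = shock, ordering = rev(vn))
  list(max_abs_difference = max(abs(r1$point - r2$point)),
       ordering_1 = r1$point, ordering_2 = r2$point)
}

#' Forecast-error variance decomposition
#'
#' Shares of each variable's h-step forecast-error variance attributable
#' to orthogonalized shocks in each of the two variables, for horizons
#' `1..H`:
#' `share_j(i, h) = sum_{k<h} (Phi_k P)[i,j]^2 / sum_{k<h} sum_j (...)^2`.
#' Rows are normalized, so the two shares sum to one at every horizon.
#'
#' @inheritParams irf
#' @return object of class `idiovar_fevd`: a named list (one element per
#'   variable) of `H` x 2 matrices of shares, plus `ordering`.
#' @export
fevd <- function(fit, H = 10L, ordering = NULL) {
  stopifnot(inherits(fit, "idiovar"))
  vn <- fit$var_names
  if (is.null(ordering)) ordering <- vn
  perm <- match(ordering, vn)
  P <- chol_factor(fit$resid_cov, perm)
  Phi <- ma_coefficients(fit, H - 1L)
  theta2 <- lapply(Phi, function(M) (M %*% P)^2)
  out <- lapply(1:2, function(i) {
    acc <- matrix(0, H, 2L, dimnames = list(paste0("h", 1:H), vn))
    run <- c(0, 0)
    for (h in seq_len(H)) {
      run <- run + theta2[[h]][i, ]
      acc[h, ] <- run / sum(run)
    }
    acc
  })
  names(out) <- vn
  structure(list(shares = out, ordering = ordering),
            class = "idiovar_fevd")
}

#' @export
print.idiovar_fevd <- function(x, digits = 3, ...) {
  for (v in names(x$shares)) {
    cat("Forecast-error variance of ", v, " explained by:\n", sep = "")
    print(round(x$shares[[v]], digits))
  }
  invisible(x)
}
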