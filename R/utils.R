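# Internal helpers shared across modules.

#' Companion matrix of a VAR(p)
#'
#' Stacks the lag-coefficient matrices of a k-variable VAR(p) into the
#' (k*p) x (k*p) companion form whose eigenvalues determine stationarity.
#'
#' @param coef_matrices list of p square coefficient matrices (k x k),
#'   element `[i, j]` of matrix `k` being the effect of variable j at lag k
#'   on variable i.
#' @return the companion matrix.
#' @keywords internal
companion_matrix <- function(coef_matrices) {
  p <- length(coef_matrices)
  k <- nrow(coef_matrices[[1L]])
  F <- matrix(0, k * p, k * p)
  for (l in seq_len(p)) {
    F[seq_len(k), (l - 1L) * k + seq_len(k)] <- coef_matrices[[l]]
  }
  if (p > 1L) {
    F[(k + 1L):(k * p), seq_len(k * (p - 1L))] <- diag(k * (p - 1L))
  }
  F
}

#' Spectral radius of the VAR companion matrix
#'
#' @inheritParams companion_matrix
#' @return largest eigenvalue modulus; the VAR is stationary iff this is < 1.
#' @keywords internal
spectral_radius <- function(coef_matrices) {
  max(Mod(eigen(companion_matrix(coef_matrices), only.values = TRUE)$values))
}

# Half-up rounding at `digits` decimals (round() rounds half to even, which
# does not reproduce printed tables). The 1e-9 guard absorbs binary
# representation error in values such as 8.945.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Parse "HH:MM" to minutes after midnight; NA passes through.
parse_clock <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & x != ""
  if (any(ok)) {
    bad <- ok & !grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x)
    if (any(bad)) {
      stop("invalid clock time(s): ", paste(unique(x[bad]), collapse = ", "))
    }
    hh <- as.integer(sub(":.*", "", x[ok]))
    mm <- as.integer(sub(".*:", "", x[ok]))
    out[ok] <- hh * 60 + mm
  }
  out
}

# Minutes after midnight to "HH:MM"; NA passes through.
format_clock <- function(m) {
  out <- rep(NA_character_, length(m))
  ok <- !is.na(m)
  m <- m[ok] %% 1440
  out[ok] <- sprintf("%02d:%02d", m %/% 60, m %% 60)
  out
}

#' Analytic autocovariances of a stationary VAR
#'
#' Solves the Yule-Walker relations through the companion form: the lag-0
#' autocovariance of the stacked VAR(1) satisfies a discrete Lyapunov
#' equation, solved by vectorisation; higher lags follow by recursion
#' Gamma(h) = F Gamma(h-1).
#'
#' @param coef_matrices list of p k x k lag-coefficient matrices.
#' @param resid_cov k x k innovation covariance.
#' @param max_lag highest lag h for which Gamma(h) is returned.
#' @return list of matrices `Gamma0 ... Gamma<max_lag>`, where
#'   `Gamma(h) = Cov(y_t, y_{t-h})`.
#' @export
var_autocovariance <- function(coef_matrices, resid_cov, max_lag = 5L) {
  k <- nrow(resid_cov)
  p <- length(coef_matrices)
  F <- companion_matrix(coef_matrices)
  kp <- k * p
  Sig <- matrix(0, kp, kp)
  Sig[seq_len(k), seq_len(k)] <- resid_cov
  G0 <- matrix(solve(diag(kp^2) - kronecker(F, F), as.vector(Sig)), kp, kp)
  out <- vector("list", max_lag + 1L)
  Gh <- G0
  out[[1L]] <- G0[seq_len(k), seq_len(k)]
  for (h in seq_len(max_lag)) {
    Gh <- F %*% Gh
    out[[h + 1L]] <- Gh[seq_len(k), seq_len(k)]
  }
  names(out) <- paste0("Gamma", 0:max_lag)
  out
}
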