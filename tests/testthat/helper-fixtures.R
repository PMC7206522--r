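# Shared fixtures: quick ground truths and random stable fits, all built
# in code at test time.

# Truth with unit-scale variables, handy for statistical checks.
unit_truth <- function(A = matrix(c(0.5, 0.2, 0.1, 0.4), 2, 2, byrow = TRUE),
                       Sigma = diag(2), n_days = 170L, seed = 1L, ...) {
  synthetic_truth(coef_matrices = if (is.list(A)) A else list(A),
                  lag_order = if (is.list(A)) length(A) else 1L,
                  intercepts = c(0, 0), resid_cov = Sigma,
                  n_days = n_days, seed = seed, strict_days = FALSE, ...)
}

# Random stationary lag matrices: scale a random draw under radius 1.
random_stable_A <- function(p = 1L, target_radius = 0.8) {
  A <- replicate(p, matrix(stats::runif(4, -0.5, 0.5), 2, 2),
                 simplify = FALSE)
  rho <- idiovar:::spectral_radius(A)
  if (rho >= target_radius) {
    A <- lapply(seq_along(A),
                function(l) A[[l]] * (target_radius / rho)^l)
  }
  A
}

random_spd <- function() {
  M <- matrix(stats::rnorm(4), 2, 2)
  crossprod(M) + diag(0.5, 2)
}

# Random stable fitted VAR: simulate from a random truth and fit.
random_stable_fit <- function(p = sample(1:2, 1), n = 300L) {
  repeat {
    A <- random_stable_A(p)
    tr <- unit_truth(A = A, Sigma = random_spd(), n_days = n,
                     seed = sample.int(1e6, 1))
    fit <- tryCatch(idiovar(simulate_latent(tr), p = p),
                    error = function(e) NULL)
    if (!is.null(fit) && check_stability(fit)$stable) return(fit)
  }
}

# Per-patient significance flags and signs reproducing the reported
# association counts of the motivating study (used to exercise
# classify_associations).
reported_association_flags <- function() {
  row <- function(pid, model, dir, sig, sign) {
    data.frame(patient_id = pid, model = model, direction = dir,
               significant = sig, sign = sign, stringsAsFactors = FALSE)
  }
  rbind(
    # TIB model: 3 positive sleep->dep; 3 positive + 1 negative dep->sleep
    row(3, "TIB", "sleep_to_dep", TRUE, "positive"),
    row(6, "TIB", "sleep_to_dep", TRUE, "positive"),
    row(20, "TIB", "sleep_to_dep", TRUE, "positive"),
    row(10, "TIB", "dep_to_sleep", TRUE, "positive"),
    row(11, "TIB", "dep_to_sleep", TRUE, "positive"),
    row(14, "TIB", "dep_to_sleep", TRUE, "positive"),
    row(19, "TIB", "dep_to_sleep", TRUE, "negative"),
    row(5, "TIB", "sleep_to_dep", FALSE, "positive"),
    # TST model: 3 positive + 3 negative sleep->dep; 2 positive + 1
    # negative dep->sleep
    row(6, "TST", "sleep_to_dep", TRUE, "positive"),
    row(20, "TST", "sleep_to_dep", TRUE, "positive"),
    row(12, "TST", "sleep_to_dep", TRUE, "positive"),
    row(7, "TST", "sleep_to_dep", TRUE, "negative"),
    row(14, "TST", "sleep_to_dep", TRUE, "negative"),
    row(19, "TST", "sleep_to_dep", TRUE, "negative"),
    row(2, "TST", "dep_to_sleep", TRUE, "positive"),
    row(11, "TST", "dep_to_sleep", TRUE, "positive"),
    row(22, "TST", "dep_to_sleep", TRUE, "negative"),
    row(5, "TST", "dep_to_sleep", FALSE, "negative"))
}
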