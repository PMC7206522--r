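test_that("lag selection stays inside 1..max_lag and needs enough data", {
  set.seed(41)
  Y <- simulate_latent(unit_truth(n_days = 300))
  p <- select_lag(Y, max_lag = 7)
  expect_true(p %in% 1:7)
  expect_error(select_lag(Y[1:20, ], max_lag = 7), "too short")
  expect_warning(select_lag(Y[1:60, ], max_lag = 7), "recommended")
})

test_that("AIC recovers a strong VAR(2) order and never under-selects", {
  A1 <- matrix(c(0.2, 0, 0, 0.2), 2)
  A2 <- matrix(c(0.45, 0.15, 0.15, 0.4), 2, 2, byrow = TRUE)
  tr <- unit_truth(A = list(A1, A2), n_days = 2000)
  set.seed(21)
  ps <- replicate(100, select_lag(simulate_latent(tr), 7))
  expect_gte(mean(ps == 2), 0.80)  # AIC over-selects with fixed probability
  expect_equal(sum(ps < 2), 0L)    # the strong lag-2 signal is never missed
})

test_that("bivariate white noise selects the smallest candidate most often", {
  set.seed(42)
  ps <- replicate(100, select_lag(cbind(rnorm(2000), rnorm(2000)), 7))
  expect_equal(as.integer(names(which.max(table(ps)))), 1L)
})

test_that("noise-free VAR(1) data are recovered to machine precision", {
  A <- matrix(c(0.5, 0.2, 0.1, 0.4), 2, 2, byrow = TRUE)
  Y <- matrix(0, 60, 2)
  Y[1, ] <- c(3, 7)
  for (t in 2:60) Y[t, ] <- c(0.3, -0.2) + A %*% Y[t - 1, ]
  fit <- idiovar(Y, p = 1)
  expect_lt(max(abs(fit$coef_matrices[[1]] - A)), 1e-10)
  expect_lt(max(abs(fit$intercepts - c(0.3, -0.2))), 1e-10)
  expect_lt(max(abs(fit$resid_cov)), 1e-16)
})

test_that("OLS estimates match the lm() normal-equations oracle", {
  set.seed(43)
  for (i in 1:50) {
    p <- sample(1:3, 1)
    fit <- random_stable_fit(p = p, n = 60L)
    d <- idiovar:::var_design(fit$y, p)
    for (eq in 1:2) {
      oracle <- unname(coef(lm(d$y[, eq] ~ d$X - 1)))
      expect_lt(max(abs(unname(fit$B[, eq]) - oracle)), 1e-8)
    }
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  Y <- cbind(a = rnorm(100), b = rep(2, 100))
  expect_error(idiovar(Y, p = 1), "rank deficient")
  expect_error(idiovar(cbind(rnorm(10), rnorm(10), rnorm(10)), p = 1),
               "two series")
  Yna <- cbind(rnorm(100), rnorm(100))
  Yna[5, 1] <- NA
  expect_error(idiovar(Yna, p = 1), "complete")
})

test_that("stability flag follows the companion spectral radius", {
  expect_equal(check_stability(list(matrix(0, 2, 2)))$spectral_radius, 0)
  unit <- check_stability(list(diag(2)))
  expect_equal(unit$spectral_radius, 1)
  expect_false(unit$stable)
  set.seed(44)
  for (i in 1:10) {
    p <- sample(1:3, 1)
    A <- random_stable_A(p)
    # brute-force oracle: assemble the 2p x 2p companion matrix here
    k <- 2
    Fm <- matrix(0, k * p, k * p)
    for (l in seq_len(p)) Fm[1:k, (l - 1) * k + 1:k] <- A[[l]]
    if (p > 1) Fm[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
    oracle <- max(Mod(eigen(Fm)$values))
    expect_equal(check_stability(A)$spectral_radius, oracle,
                 tolerance = 1e-12)
  }
})

test_that("Granger F statistic equals the independent lmtest oracle", {
  skip_if_not_installed("lmtest")
  set.seed(45)
  for (i in 1:10) {
    n <- 150
    x <- as.numeric(arima.sim(list(ar = 0.4), n + 1))
    y <- 0.4 * x[1:n] + rnorm(n)
    Y <- cbind(x = x[2:(n + 1)], y = y)
    p <- sample(1:3, 1)
    g <- granger_test(idiovar(Y, p = p), "x", "y")
    oracle <- lmtest::grangertest(Y[, "y"] ~ Y[, "x"], order = p)
    expect_equal(g$statistic, oracle$F[2], tolerance = 1e-10)
    expect_equal(g$p_value, oracle$`Pr(>F)`[2], tolerance = 1e-10)
  }
})

test_that("unrestricted RSS never exceeds restricted RSS", {
  set.seed(46)
  for (i in 1:20) {
    fit <- random_stable_fit(n = 120L)
    g <- granger_test(fit, fit$var_names[1], fit$var_names[2])
    expect_gte(g$statistic, 0)
    expect_true(g$p_value >= 0 && g$p_value <= 1)
  }
})

test_that("Granger power grows with the cross-coefficient and flags its sign", {
  set.seed(47)
  rate <- vapply(c(0, 0.2, 0.5), function(b) {
    mean(replicate(60, {
      x <- as.numeric(arima.sim(list(ar = 0.5), 171))
      y <- b * x[1:170] + rnorm(170)
      fit <- idiovar(cbind(x = x[2:171], y = y), p = 1)
      granger_test(fit, "x", "y")$p_value < 0.05
    }))
  }, numeric(1))
  expect_lt(rate[1], 0.15)
  expect_gt(rate[3], rate[1])
  expect_gt(rate[3], 0.9)

  x <- as.numeric(arima.sim(list(ar = 0.5), 171))
  y <- 0.8 * x[1:170] + rnorm(170)
  g <- granger_test(idiovar(cbind(x = x[2:171], y = y), p = 1), "x", "y")
  expect_true(g$significant)
  expect_equal(g$association_sign, "positive")
})

test_that("fit methods behave coherently", {
  set.seed(48)
  fit <- random_stable_fit(p = 2, n = 250L)
  expect_equal(dim(coef(fit)), c(5L, 2L))
  expect_equal(nrow(residuals(fit)), fit$n_effective)
  expect_equal(AIC(fit), fit$aic)
  fc <- predict(fit, n_ahead = 5)
  expect_equal(dim(fc), c(5L, 2L))
  # long-horizon forecast converges to the process mean for a stable VAR
  mu <- solve(diag(2) - Reduce(`+`, fit$coef_matrices), fit$intercepts)
  expect_lt(max(abs(predict(fit, n_ahead = 200)[200, ] - mu)), 1e-6)
  sim <- simulate(fit, seed = 1, n = 500)
  expect_equal(dim(sim), c(500L, 2L))
  expect_identical(sim, simulate(fit, seed = 1, n = 500))
})
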