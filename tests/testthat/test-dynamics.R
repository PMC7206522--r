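test_that("MA recursion has the right degenerate and closed forms", {
  zero <- list(matrix(0, 2, 2))
  Phi <- ma_coefficients(zero, H = 4)
  expect_identical(Phi[[1]], diag(2))
  for (h in 2:5) expect_identical(Phi[[h]], matrix(0, 2, 2))

  A <- matrix(c(0.5, 0.2, 0.1, 0.4), 2, 2, byrow = TRUE)
  Phi1 <- ma_coefficients(list(A), H = 5)
  Ah <- diag(2)
  for (h in 1:5) {
    Ah <- Ah %*% A
    expect_equal(Phi1[[h + 1]], Ah, tolerance = 1e-12)
  }
})

test_that("IRF equals the deterministic shock-simulation oracle", {
  set.seed(51)
  for (i in 1:10) {
    fit <- random_stable_fit()
    P <- t(chol(fit$resid_cov))
    H <- 10
    p <- fit$p
    # oracle: hit the system with the orthogonal shock and iterate the
    # fitted difference equation with no further innovations
    y <- matrix(0, H + p + 1, 2)
    y[p + 1, ] <- P[, 1]
    for (t in (p + 2):(H + p + 1)) {
      for (l in seq_len(p)) {
        y[t, ] <- y[t, ] + fit$coef_matrices[[l]] %*% y[t - l, ]
      }
    }
    oracle <- y[(p + 1):(H + p + 1), 2]
    r <- irf(fit, fit$var_names[1], fit$var_names[2], H = H,
             shock = "orthogonal")
    expect_lt(max(abs(r$point - oracle)), 1e-8)
    expect_equal(r$cumulative, cumsum(r$point))
  }
})

test_that("uncoupled variables show exactly zero cross-response", {
  tr <- unit_truth(A = matrix(c(0.5, 0, 0, 0.4), 2, 2),
                   Sigma = diag(c(2, 1)))
  fit <- idiovar(simulate_latent(tr), p = 1)
  fit$coef_matrices[[1]][1, 2] <- 0  # exact null for the closed-form check
  fit$coef_matrices[[1]][2, 1] <- 0
  fit$resid_cov <- diag(diag(fit$resid_cov))
  r <- irf(fit, "sleep", "dep", H = 10)
  expect_equal(unname(r$point), rep(0, 11))
})

test_that("a pure lag-1 coupling gives response b at horizon 1", {
  b <- 0.37
  fit <- random_stable_fit(p = 1, n = 200L)
  fit$coef_matrices[[1]] <- matrix(c(0, 0, b, 0), 2, 2, byrow = TRUE)
  fit$resid_cov <- diag(2)
  r <- irf(fit, fit$var_names[1], fit$var_names[2], H = 5,
           shock = "orthogonal")
  expect_equal(unname(r$point[1:2]), c(0, b), tolerance = 1e-12)
})

test_that("cumulative responses of stable fits flatten geometrically", {
  set.seed(52)
  for (i in 1:5) {
    fit <- random_stable_fit()
    r <- irf(fit, fit$var_names[1], fit$var_names[2], H = 10)
    d <- abs(diff(r$cumulative))
    expect_lt(d[10], d[2] + 1e-12)
    # tail differences shrink relative to the largest step
    expect_lt(d[10], 0.5 * max(d) + 1e-12)
  }
})

test_that("shock scaling: horizon-0 own response is 1 SD of the series", {
  set.seed(53)
  fit <- random_stable_fit()
  own <- irf(fit, fit$var_names[1], fit$var_names[1], H = 3)
  expect_equal(own$point[1], sd(fit$y[, 1]), tolerance = 1e-12)
})

test_that("bootstrap bands are reproducible, cover the point, narrow with n", {
  tr <- unit_truth(A = matrix(c(0.4, 0.1, 0.2, 0.3), 2, 2, byrow = TRUE),
                   n_days = 150, seed = 9)
  fit <- idiovar(simulate_latent(tr), p = 1)
  b1 <- irf(fit, "sleep", "dep", boot = TRUE, runs = 200, seed = 5)
  b2 <- irf(fit, "sleep", "dep", boot = TRUE, runs = 200, seed = 5)
  expect_identical(b1$lower, b2$lower)
  expect_identical(b1$upper, b2$upper)
  expect_true(all(b1$lower <= b1$point + 1e-12))
  expect_true(all(b1$point <= b1$upper + 1e-12))
  expect_true(all(b1$cum_lower <= b1$cumulative + 1e-12))

  tr2 <- unit_truth(A = tr$coef_matrices[[1]], n_days = 1500, seed = 9)
  fit2 <- idiovar(simulate_latent(tr2), p = 1)
  b3 <- irf(fit2, "sleep", "dep", boot = TRUE, runs = 200, seed = 5)
  expect_lt(mean(b3$upper - b3$lower), mean(b1$upper - b1$lower))
})

test_that("FEVD shares are proper at every horizon on random stable fits", {
  set.seed(54)
  for (i in 1:20) {
    fit <- random_stable_fit()
    f <- fevd(fit, H = 10)
    for (v in fit$var_names) {
      sh <- f$shares[[v]]
      expect_true(all(sh >= 0))
      expect_lt(max(abs(rowSums(sh) - 1)), 1e-9)
    }
    # recursive identification: the first-ordered variable owns all of its
    # horizon-1 forecast-error variance
    expect_equal(unname(f$shares[[fit$var_names[1]]][1, 1]), 1)
  }
})

test_that("FEVD cross share rises from horizon 1 then plateaus under lag-1 coupling", {
  tr <- unit_truth(A = matrix(c(0.3, 0, 0.25, 0.3), 2, 2, byrow = TRUE),
                   Sigma = diag(2), n_days = 3000, seed = 12)
  fit <- idiovar(simulate_latent(tr), p = 1)
  cross <- fevd(fit, H = 10)$shares$dep[, "sleep"]
  expect_lt(cross[1], 0.02)           # nothing at horizon 1
  expect_gt(cross[3], cross[1])       # rises
  expect_lt(abs(cross[10] - cross[4]), 0.01)  # flat tail
})

test_that("near-diagonal residual covariance makes ordering immaterial", {
  tr <- unit_truth(A = matrix(c(0.4, 0.1, 0.2, 0.3), 2, 2, byrow = TRUE),
                   Sigma = diag(c(1, 2)), n_days = 5000, seed = 13)
  fit <- idiovar(simulate_latent(tr), p = 1)
  s <- ordering_sensitivity(fit, "sleep", "dep")
  expect_lt(s$max_abs_difference, 0.05 * sd(fit$y[, "dep"]))
})

test_that("unstable fits are flagged on the way into the dynamics", {
  fit <- random_stable_fit(p = 1, n = 150L)
  fit$coef_matrices[[1]] <- diag(2) * 1.01
  expect_warning(ma_coefficients(fit, H = 5), "unstable")
})
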