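test_that("pairwise distances are a metric and equivariant", {
  Z <- rbind(c(0, 0), c(3, 4), c(1, 1))
  D <- pairwise_distances(Z)
  expect_equal(D[1, 2], 5)
  expect_true(all(diag(D) == 0))
  expect_equal(D, t(D))
  pm <- c(2, 3, 1)
  expect_equal(pairwise_distances(Z[pm, ]), D[pm, pm], ignore_attr = TRUE)
  expect_error(pairwise_distances(rbind(c(NA, 1), c(0, 0))), "non-finite")
})

test_that("adaptive bandwidth is the k-th neighbor distance, self excluded", {
  Z <- matrix(c(0, 1, 3))
  D <- pairwise_distances(Z)
  expect_equal(adaptive_bandwidth(D, 1), c(1, 1, 2))
  # k = n - 1 gives the maximum distance from each point
  expect_equal(adaptive_bandwidth(D, 2), c(3, 2, 3))
  # duplicated point with k = 1 is degenerate
  Dd <- pairwise_distances(matrix(c(0, 0, 3)))
  expect_error(adaptive_bandwidth(Dd, 1), "raise `k` or jitter")
  expect_error(adaptive_bandwidth(D, 3), "k <= n - 1")
})

test_that("Gaussian kernel weights follow the scaled-distance formula", {
  Z <- matrix(c(0, 1, 3))
  D <- pairwise_distances(Z)
  dk <- adaptive_bandwidth(D, 1)
  lw <- kernel_weights(D, dk, kernel_spec(sigma = 1))
  expect_true(all(diag(lw$W) == 1))
  # neighbor exactly at the k-th distance: u = 1 -> exp(-1/2)
  expect_equal(lw$W[1, 2], exp(-0.5))
  expect_equal(lw$W[3, 2], exp(-0.5))
  # decreasing in distance within a row
  expect_lt(lw$W[1, 3], lw$W[1, 2])
  # sigma -> Inf: all weights -> 1 (global limit)
  w_inf <- kernel_weights(D, dk, kernel_spec(sigma = 1e9))$W
  expect_equal(max(abs(w_inf - 1)), 0, tolerance = 1e-10)
  # tricube vanishes beyond the bandwidth
  wt <- kernel_weights(D, dk, kernel_spec("tricube", k = 1))$W
  expect_equal(wt[1, 3], 0)
  expect_equal(wt[1, 1], 1)
})

test_that("local WLS equals OLS under uniform weights and handles
           degenerate designs", {
  fx <- make_latent_fixture(n = 25, d = 2, seed = 21)
  w <- rep(1, 25)
  beta <- fit_local_wls(fx$Z, fx$y, w, ridge_eps = 0)
  ols <- unname(coef(lm(fx$y ~ fx$Z)))
  expect_equal(beta, ols, tolerance = 1e-8, ignore_attr = TRUE)
  # constant outcome -> intercept only
  beta_c <- fit_local_wls(fx$Z, rep(2.5, 25), w, ridge_eps = 0)
  expect_equal(beta_c, c(2.5, 0, 0), tolerance = 1e-10, ignore_attr = TRUE)
  # singular design: duplicated column
  Zs <- cbind(fx$Z[, 1], fx$Z[, 1])
  expect_error(fit_local_wls(Zs, fx$y, w, ridge_eps = 0), "ridge_eps")
  expect_silent(fit_local_wls(Zs, fx$y, w, ridge_eps = 1e-6))
  expect_error(fit_local_wls(fx$Z, fx$y, rep(0, 25)), "weights")
})

test_that("closed-form WLS agrees with brute-force minimization", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:30, 1); d <- sample(1:3, 1)
    Z <- matrix(rnorm(n * d), n, d)
    y <- rnorm(n)
    w <- runif(n, 0.05, 1)
    beta <- fit_local_wls(Z, y, w, ridge_eps = 0)
    oracle <- wls_numeric_oracle(Z, y, w, start = beta + rnorm(d + 1, sd = 0.1))
    expect_equal(beta, oracle, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("local null fit is the weighted mean", {
  expect_equal(fit_local_null(c(0, 0, 3), c(1, 1, 2)), 1.5)
  y <- rnorm(10)
  expect_equal(fit_local_null(y, rep(1, 10)), mean(y))
  # point mass recovers that patient's outcome
  w <- c(1, rep(1e-12, 9))
  expect_equal(fit_local_null(y, w), y[1], tolerance = 1e-9)
})

test_that("likelihood-ratio closed form equals direct log-likelihood
           difference and respects nesting", {
  set.seed(15)
  n <- 15
  Z <- matrix(rnorm(n * 2), n, 2)
  y <- drop(Z %*% c(1, -0.5)) + rnorm(n, sd = 0.5)
  w <- runif(n, 0.1, 1)
  beta <- fit_local_wls(Z, y, w, ridge_eps = 0)
  b0 <- fit_local_null(y, w)
  rf <- y - drop(cbind(1, Z) %*% beta)
  rn <- y - b0
  lr <- neg_log_likelihood_ratio(w, rf, rn)
  direct <- weighted_gauss_loglik(w, rn) - weighted_gauss_loglik(w, rf)
  expect_equal(lr$neg_log_ratio, direct, tolerance = 1e-8)
  expect_lte(lr$neg_log_ratio, 0)
  expect_lte(lr$sigma2_full, lr$sigma2_null)
  # locally constant outcome -> warned, zero contribution
  expect_warning(
    out <- neg_log_likelihood_ratio(w, rf, rep(0, n)),
    "locally constant")
  expect_equal(out$neg_log_ratio, 0)
  # perfect linear fit -> variance floored, strongly negative
  lr_perf <- neg_log_likelihood_ratio(w, rep(0, n), rn)
  expect_equal(lr_perf$sigma2_full, 1e-8)
  expect_lt(lr_perf$neg_log_ratio, -10)
})

test_that("nesting holds for every patient on random instances", {
  fx <- make_latent_fixture(n = 40, d = 2, seed = 33)
  lf <- fit_local_all(fx$Z, fx$y, kernel_spec(sigma = 1, k = 10))
  expect_true(all(lf$sigma2_full <= lf$sigma2_null + 1e-12))
  expect_true(all(lf$neg_log_ratio <= 1e-12))
})

test_that("sigma -> Inf recovers the global OLS coefficients", {
  fx <- make_latent_fixture(n = 50, d = 3, seed = 44)
  lf <- fit_local_all(fx$Z, fx$y, kernel_spec(sigma = 1e6, k = 15),
                      ridge_eps = 0)
  ols <- unname(coef(lm(fx$y ~ fx$Z)))
  expect_lt(max(abs(sweep(lf$beta, 2, ols, "-"))), 1e-4)
})

test_that("prediction loss is nonpositive, scale-invariant in y, and
           smaller when the latent carries outcome signal", {
  fx <- make_latent_fixture(n = 40, d = 2, seed = 55)
  ks <- kernel_spec(sigma = 1, k = 10)
  loss_signal <- prediction_loss(fx$Z, fx$y, ks)
  expect_lte(loss_signal, 0)
  # scaling y leaves the variance-ratio loss unchanged
  expect_equal(prediction_loss(fx$Z, fx$y * 7.3, ks), loss_signal,
               tolerance = 1e-10)
  # outcome independent of the latent -> loss much closer to zero
  set.seed(56)
  loss_noise <- prediction_loss(fx$Z, rnorm(40), ks)
  expect_lt(loss_signal, loss_noise)
  # duplicate latent rows are rejected through the bandwidth
  Zdup <- fx$Z; Zdup[2, ] <- Zdup[1, ]
  expect_error(prediction_loss(Zdup, fx$y, kernel_spec(k = 1)),
               "raise `k` or jitter")
})

test_that("analytic gradient of the prediction loss matches central
           finite differences", {
  set.seed(66)
  n <- 12; d <- 2
  Z <- matrix(rnorm(n * d), n, d)
  y <- drop(Z %*% c(0.8, -0.5)) + rnorm(n, sd = 0.4)
  ks <- kernel_spec(sigma = 1, k = 4)
  g <- latentlocal:::prediction_loss_grad(Z, y, ks)
  h <- 1e-5
  fd <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) for (l in seq_len(d)) {
    Zp <- Z; Zp[i, l] <- Zp[i, l] + h
    Zm <- Z; Zm[i, l] <- Zm[i, l] - h
    fd[i, l] <- (prediction_loss(Zp, y, ks) -
                   prediction_loss(Zm, y, ks)) / (2 * h)
  }
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-3)
})
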