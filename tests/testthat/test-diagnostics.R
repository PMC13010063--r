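test_that("global fit matches the reference OLS implementation", {
  fx <- make_latent_fixture(n = 60, d = 3, seed = 71)
  g <- fit_global(fx$Z, fx$y)
  ref <- lm(fx$y ~ fx$Z)
  expect_equal(g$coefficients, unname(coef(ref)), tolerance = 1e-8)
  ci <- unname(confint(ref))
  expect_equal(g$ci_lower, ci[, 1], tolerance = 1e-8)
  expect_equal(g$ci_upper, ci[, 2], tolerance = 1e-8)
  expect_equal(g$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  expect_true(all(g$ci_lower <= g$coefficients &
                    g$coefficients <= g$ci_upper))
})

test_that("global fit edge cases: noiseless and unrelated outcomes", {
  set.seed(72)
  Z <- matrix(rnorm(40), 20, 2)
  g <- suppressWarnings(fit_global(Z, 2 * Z[, 1]))  # lm warns on exact fit
  expect_equal(g$coefficients[2], 2, tolerance = 1e-8)
  expect_equal(g$r_squared, 1, tolerance = 1e-10)
  expect_lt(g$ci_upper[2] - g$ci_lower[2], 1e-6)
  # independent outcome at large n
  Zbig <- matrix(rnorm(4000), 2000, 2)
  expect_lt(fit_global(Zbig, rnorm(2000))$r_squared, 0.05)
  expect_error(fit_global(cbind(Z[, 1], Z[, 1]), rnorm(20)),
               "rank-deficient")
})

test_that("deviation profile flags strictly outside the CI", {
  g <- structure(list(coefficients = c(0, 1), ci_lower = c(-0.5, 0.8),
                      ci_upper = c(0.5, 1.2), r_squared = 0.5, sigma = 1,
                      fitted = numeric(0), level = 0.95, d = 1L),
                 class = "global_fit")
  lf <- structure(list(beta = cbind(0, c(1, 1.2, 1.21, 0.79, 0.8, 1.5))),
                  class = "local_fits")
  prof <- deviation_profile(lf, g)
  expect_equal(prof$difference, prof$beta_local - prof$beta_global)
  # boundary values (1.2, 0.8) are not flagged; strictly outside are
  expect_equal(prof$flag, c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_true(all(abs(prof$difference[prof$flag]) > 0))
  # local equal to global -> nothing flagged
  lf0 <- structure(list(beta = cbind(0, rep(1, 4))), class = "local_fits")
  expect_true(!any(deviation_profile(lf0, g)$flag))
})

test_that("widening the CI level never increases the number of flags", {
  fx <- make_latent_fixture(n = 60, d = 2, noise = 1, seed = 73)
  lf <- fit_local_all(fx$Z, fx$y, kernel_spec(sigma = 1, k = 15))
  n95 <- sum(deviation_profile(lf, fit_global(fx$Z, fx$y, 0.95))$flag)
  n99 <- sum(deviation_profile(lf, fit_global(fx$Z, fx$y, 0.99))$flag)
  expect_lte(n99, n95)
})

test_that("subgroups collect same-dimension same-sign flags above the
           minimum size", {
  prof <- data.frame(
    patient = rep(1:60, 2), dim = rep(1:2, each = 60),
    beta_local = 0, beta_global = 0,
    difference = c(rep(1, 30), rep(0, 30), rep(-1, 20), rep(0, 37),
                   rep(1, 3)),
    flag = c(rep(TRUE, 30), rep(FALSE, 30), rep(TRUE, 20), rep(FALSE, 37),
             rep(TRUE, 3)),
    sign = c(rep(1, 30), rep(0, 30), rep(-1, 20), rep(0, 37), rep(1, 3)))
  class(prof) <- c("deviation_profile", "data.frame")
  sgs <- form_subgroups(prof, min_size = 5)
  expect_length(sgs$subgroups, 2)
  expect_equal(sgs$subgroups[[1]]$size, 30)   # sorted, largest first
  expect_equal(sgs$subgroups[[1]]$dim, 1)
  expect_equal(sgs$subgroups[[2]]$size, 20)
  expect_equal(sgs$subgroups[[2]]$sign, -1)
  # the 3 small-count flags are reported as unassigned, not a subgroup
  expect_equal(nrow(sgs$unassigned), 3)
  # membership consistency: every member flagged on the dim with the sign
  for (sg in sgs$subgroups) {
    rows <- prof[prof$dim == sg$dim & prof$patient %in% sg$members, ]
    expect_true(all(rows$flag & rows$sign == sg$sign))
  }
  # no flags -> empty list
  prof0 <- prof; prof0$flag <- FALSE
  expect_length(form_subgroups(prof0)$subgroups, 0)
})

test_that("latent-predictor correlations behave as correlations", {
  set.seed(74)
  X <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  Z <- cbind(X[, 3], rnorm(200))
  lc <- latent_correlation(Z, X, m = 2)
  expect_equal(unname(lc$correlation[1, 3]), 1, tolerance = 1e-12)
  expect_equal(names(lc$top[[1]])[1], "x3")
  # sign flip of a latent dim flips its correlation row
  lc2 <- latent_correlation(cbind(-Z[, 1], Z[, 2]), X, m = 2)
  expect_equal(lc2$correlation[1, ], -lc$correlation[1, ])
  # independent columns at large n stay near zero
  expect_lt(max(abs(lc$correlation[2, ])), 0.25)
  # zero-variance latent dim is warned and zeroed
  expect_warning(lcz <- latent_correlation(cbind(Z[, 1], 0), X),
                 "zero-variance")
  expect_true(all(lcz$correlation[2, ] == 0))
})

test_that("Z-score profiles contrast subgroups against a zero cohort mean", {
  set.seed(75)
  X <- standardize(matrix(rnorm(100 * 6), 100, 6), rnorm(100))$X
  # full cohort: zero profile by construction of the standardization
  expect_lt(max(abs(zscore_profile(X, 1:100)$profile)), 1e-10)
  # single patient: their own row
  expect_equal(unname(zscore_profile(X, 7)$profile), X[7, ],
               ignore_attr = TRUE)
  expect_error(zscore_profile(X, integer(0)), "empty")
  # planted covariate shift is recovered
  Xs <- X; Xs[1:20, 5] <- Xs[1:20, 5] + 1
  Xs <- standardize(Xs, rnorm(100))$X
  expect_gt(zscore_profile(Xs, 1:20)$profile[5], 0.5)
})

test_that("predictor clustering recovers correlation blocks", {
  set.seed(76)
  base <- matrix(rnorm(150 * 4), 150, 4)
  X <- base[, rep(1:4, each = 3)] + matrix(rnorm(150 * 12, sd = 0.2),
                                           150, 12)
  cl <- cluster_predictors(X, n_clusters = 4)
  expect_equal(length(unique(cl)), 4)
  truth <- rep(1:4, each = 3)
  # same-block pairs share a cluster, cross-block pairs do not
  for (b in 1:4)
    expect_equal(length(unique(cl[truth == b])), 1)
  # perfectly correlated predictors always merge
  X2 <- cbind(X, X[, 1])
  cl2 <- cluster_predictors(X2, n_clusters = 6)
  expect_equal(cl2[13], cl2[1])
  # n_clusters = p gives singletons
  expect_equal(length(unique(cluster_predictors(X, 12))), 12)
  expect_error(cluster_predictors(cbind(X, 0), 4), "constant")
})

test_that("interaction analysis detects a planted subgroup interaction and
           is calibrated under the null", {
  set.seed(77)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  members <- 1:60
  g <- as.numeric(seq_len(n) %in% members)
  y <- X[, 1] + 1.5 * X[, 1] * g + rnorm(n, sd = 0.5)
  res <- interaction_analysis(X, y, members, c("x1", "x2"))
  est <- res$estimate[res$predictor == "x1"]
  expect_equal(est, 1.5, tolerance = 0.3)
  expect_lt(res$p_value[res$predictor == "x1"], 0.01)
  expect_true(all(c("p_value", "p_adj") %in% names(res)))
  # type-I calibration: membership independent of (x, y)
  set.seed(78)
  rej <- mean(replicate(200, {
    yy <- rnorm(100); xx <- matrix(rnorm(100), 100, 1,
                                   dimnames = list(NULL, "x1"))
    mem <- sample(100, 30)
    interaction_analysis(xx, yy, mem, "x1")$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.05)
  expect_error(interaction_analysis(X, y, 1:n, "x1"), "constant")
})

test_that("RMSE contrast separates inside and outside improvements", {
  set.seed(79)
  y <- rnorm(50)
  gfit <- y + rnorm(50, sd = 0.5)
  # local fits equal global -> zero improvement everywhere
  rc0 <- rmse_contrast(y, gfit, gfit, 1:10)
  expect_equal(rc0$inside$improvement, 0)
  expect_equal(rc0$outside$improvement, 0)
  # perfect local fits -> improvement equals the global RMSE
  rc1 <- rmse_contrast(y, gfit, y, 1:10)
  expect_equal(rc1$inside$improvement, rc1$inside$rmse_global)
  expect_equal(rc1$inside$rmse_local, 0)
  expect_equal(rc1$inside$n, 10)
  expect_error(rmse_contrast(y, gfit, y, integer(0)), "proper subset")
  expect_error(rmse_contrast(y, gfit, y, 1:50), "proper subset")
})

test_that("test projection reproduces a duplicated training patient and
           handles empty test sets", {
  fx <- make_latent_fixture(n = 40, d = 2, seed = 80)
  # a tiny trained autoencoder on synthetic predictors
  set.seed(81)
  X <- cbind(fx$Z %*% matrix(rnorm(8), 2, 4)) +
    matrix(rnorm(160, sd = 0.05), 40, 4)
  std <- standardize(X, fx$y)
  cfg <- train_config(lambda_rec = 1, lambda_pred = 0.05,
                      learning_rate = 0.01, epochs = 30, d = 2,
                      hidden = c(8, 4), kernel = kernel_spec(k = 10),
                      seed = 1)
  tr <- train(std$X, std$y, cfg)
  g <- fit_global(tr$Z_final, std$y)
  pt <- project_test(std$X[c(3, 9), ], tr$params, tr$Z_final, std$y, g,
                     spec = cfg$kernel)
  expect_equal(pt$Z_test[1, ], tr$Z_final[3, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  lf <- fit_local_all(tr$Z_final, std$y, cfg$kernel)
  # local coefficients of the duplicate are close to the training ones
  expect_equal(unname(pt$beta[1, ]), unname(lf$beta[3, ]),
               tolerance = 0.05)
  # empty test set
  pt0 <- project_test(std$X[0, , drop = FALSE], tr$params, tr$Z_final,
                      std$y, g, spec = cfg$kernel)
  expect_equal(nrow(pt0$profile), 0)
})
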