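# Small in-code fixtures shared across test files.

# latent cloud + linear outcome, well separated so k-NN bandwidths are stable
make_latent_fixture <- function(n = 20, d = 2, beta = NULL, noise = 0.3,
                                seed = 11) {
  set.seed(seed)
  if (is.null(beta)) beta <- seq_len(d)
  Z <- matrix(rnorm(n * d), n, d)
  y <- drop(Z %*% beta) + rnorm(n, sd = noise)
  list(Z = Z, y = y, beta = beta)
}

# brute-force minimizer of the patient-specific weighted SSE (independent
# oracle for the closed-form WLS solution)
wls_numeric_oracle <- function(Z, y, w, start = NULL) {
  V <- cbind(1, Z)
  obj <- function(b) sum(w * (y - drop(V %*% b))^2)
  if (is.null(start)) start <- rep(0, ncol(V))
  stats::optim(start, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
}

# weighted Gaussian log-likelihood with plug-in variance (independent
# oracle for the likelihood-ratio closed form)
weighted_gauss_loglik <- function(w, resid) {
  s2 <- sum(w * resid^2) / sum(w)
  sum(w * (-0.5 * log(2 * pi * s2) - resid^2 / (2 * s2)))
}
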