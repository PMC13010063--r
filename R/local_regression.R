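#' Kernel specification for localized regression
#'
#' The weight given to neighbor j when fitting patient i's local model is
#' `K(||z_i - z_j|| / d_k(z_i))`, where `d_k(z_i)` is the distance from
#' `z_i` to its k-th nearest neighbor (adaptive bandwidth). The Gaussian
#' kernel `K_G(x) = exp(-x^2 / (2 sigma^2))` is the default: it is smooth
#' and assigns nonzero weight to every patient, which stabilizes local fits
#' in sparse latent regions. A tricube kernel `(1 - u^3)^3` on `u < 1` is
#' available but discouraged — its hard cutoff tends to produce unstable
#' local models.
#'
#' @param family `"gaussian"` (default) or `"tricube"`.
#' @param sigma Positive bandwidth of the Gaussian kernel (default 1).
#' @param k Neighborhood order for the adaptive width, 1 <= k <= n - 1. The
#'   default `NULL` resolves to `ceiling(0.3 * n)` at weight time.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("gaussian", "tricube"), sigma = 1,
                        k = NULL) {
  family <- match.arg(family)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (!is.null(k) && (k < 1)) stop("`k` must be >= 1", call. = FALSE)
  structure(list(family = family, sigma = sigma,
                 k = if (is.null(k)) NULL else as.integer(k)),
            class = "kernel_spec")
}

resolve_k <- function(spec, n) {
  k <- if (is.null(spec$k)) ceiling(0.3 * n) else spec$k
  if (k > n - 1L)
    stop(sprintf("`k` = %d must be <= n - 1 = %d", k, n - 1L), call. = FALSE)
  as.integer(k)
}

#' Euclidean distance matrix between latent vectors
#'
#' @param Z n x d latent matrix, n >= 2, all entries finite.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
pairwise_distances <- function(Z) {
  Z <- rbind(Z)
  if (nrow(Z) < 2L) stop("need at least 2 patients", call. = FALSE)
  if (!all(is.finite(Z))) stop("non-finite latent values", call. = FALSE)
  as.matrix(stats::dist(Z))
}

#' Adaptive k-nearest-neighbor bandwidth
#'
#' For every patient i, the distance to its k-th nearest neighbor among the
#' other patients (the point itself is excluded — otherwise k = 1 would
#' always give a zero width). Ties are broken by a stable sort on index.
#'
#' @param distances n x n distance matrix.
#' @param k Neighbor order, 1 <= k <= n - 1.
#' @param return_index If `TRUE`, also return which neighbor attains the
#'   width (used to differentiate through the bandwidth).
#' @return Length-n positive vector `dk` (or a list with `dk` and `idx`).
#' @export
adaptive_bandwidth <- function(distances, k, return_index = FALSE) {
  n <- nrow(distances)
  if (k < 1 || k > n - 1) stop("need 1 <= k <= n - 1", call. = FALSE)
  dk <- numeric(n); idx <- integer(n)
  for (i in seq_len(n)) {
    d_i <- distances[i, -i]
    ord <- order(d_i)  # stable: ties keep index order
    j <- ord[k]
    dk[i] <- d_i[j]
    idx[i] <- if (j >= i) j + 1L else j  # undo the self-removal offset
  }
  if (any(dk == 0))
    stop("adaptive bandwidth is zero for patient(s) ",
         paste(which(dk == 0), collapse = ", "),
         " (duplicate latent points up to the k-th neighbor); ",
         "raise `k` or jitter the latent coordinates", call. = FALSE)
  if (return_index) list(dk = dk, idx = idx) else dk
}

#' Kernel weight matrix for all patients
#'
#' Row i holds the weights `w_ij` used in patient i's local fit:
#' `K(d_ij / dk_i)`. The self-weight is always `K(0) = 1`.
#'
#' @param distances n x n distance matrix.
#' @param dk Length-n adaptive bandwidths.
#' @param spec A [kernel_spec()].
#' @return Object of class `local_weights`: list with `W` (n x n) and `dk`.
#' @export
kernel_weights <- function(distances, dk, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  U <- sweep(distances, 1, dk, "/")
  W <- switch(spec$family,
    gaussian = exp(-U^2 / (2 * spec$sigma^2)),
    tricube = {
      Wt <- pmax(1 - U^3, 0)^3
      matrix(Wt, nrow(distances), ncol(distances))
    })
  structure(list(W = W, dk = dk), class = "local_weights")
}

#' Patient-specific weighted least squares fit
#'
#' Minimizes `sum_j w_j (y_j - beta0 - sum_l beta_l z_jl)^2` with an
#' intercept. A small ridge `ridge_eps` is added to the non-intercept
#' diagonal of the weighted Gram matrix for invertibility of near-singular
#' local designs; with `ridge_eps = 0` and a full-rank design this is the
#' exact WLS minimizer.
#'
#' @param Z n x d latent matrix.
#' @param y Length-n outcome.
#' @param w Length-n nonnegative weights, not all zero.
#' @param ridge_eps Ridge jitter (default 1e-6).
#' @return Length-(d + 1) coefficient vector `(beta0, beta1, ..., betad)`.
#' @export
fit_local_wls <- function(Z, y, w, ridge_eps = 1e-6) {
  Z <- rbind(Z)
  if (any(w < 0) || all(w == 0))
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  V <- cbind(1, Z)
  A <- crossprod(V, w * V)
  if (ridge_eps > 0)
    diag(A)[-1] <- diag(A)[-1] + ridge_eps
  b <- crossprod(V, w * y)
  beta <- tryCatch(solve(A, b), error = function(e)
    stop("singular weighted Gram matrix; set `ridge_eps` > 0", call. = FALSE))
  drop(beta)
}

#' Patient-specific weighted null (intercept-only) fit
#'
#' @inheritParams fit_local_wls
#' @return The weighted mean `sum(w * y) / sum(w)`.
#' @export
fit_local_null <- function(y, w) {
  if (any(w < 0) || all(w == 0))
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  sum(w * y) / sum(w)
}

#' Negative log-likelihood ratio of a local full fit versus its null fit
#'
#' Both models use the same patient-specific weights and a weighted Gaussian
#' likelihood with plug-in variance `sigma2 = sum(w e^2) / sum(w)`; the
#' ratio then collapses to the closed form
#' `(sum(w) / 2) * log(sigma2_full / sigma2_null)`, which is always <= 0
#' because the full model nests the null under the same weights. Variances
#' are floored at `floor` so a perfect local fit cannot produce -Inf; a
#' locally constant outcome (null variance at the floor) contributes 0 with
#' a warning.
#'
#' @param w Length-n weights.
#' @param residuals_full,residuals_null Residual vectors of the two fits.
#' @param floor Variance floor (default 1e-8).
#' @return List with `neg_log_ratio`, `sigma2_full`, `sigma2_null`.
#' @export
neg_log_likelihood_ratio <- function(w, residuals_full, residuals_null,
                                     floor = 1e-8) {
  S <- sum(w)
  s2f <- sum(w * residuals_full^2) / S
  s2n <- sum(w * residuals_null^2) / S
  if (s2n < floor) {
    warning("locally constant outcome: null variance below floor; ",
            "likelihood-ratio term set to 0")
    return(list(neg_log_ratio = 0, sigma2_full = max(s2f, floor),
                sigma2_null = floor))
  }
  s2f <- max(s2f, floor)
  list(neg_log_ratio = (S / 2) * log(s2f / s2n),
       sigma2_full = s2f, sigma2_null = s2n)
}

#' Fit all patient-specific local models
#'
#' Computes distances, adaptive bandwidths, kernel weights, and per-patient
#' full and null weighted fits with their likelihood-ratio terms.
#'
#' @param Z n x d latent matrix.
#' @param y Length-n standardized outcome.
#' @param spec A [kernel_spec()].
#' @param ridge_eps Ridge jitter for the local Gram matrices.
#' @param var_floor Variance floor for the likelihood ratio.
#' @return Object of class `local_fits`: list with `beta` (n x (d + 1)
#'   matrix, one row per patient), `beta_null`, `sigma2_full`,
#'   `sigma2_null`, `neg_log_ratio`, `fitted_local` (each patient's own
#'   local model evaluated at their own latent point), `weights`
#'   (`local_weights`) and `spec`.
#' @export
fit_local_all <- function(Z, y, spec = kernel_spec(), ridge_eps = 1e-6,
                          var_floor = 1e-8) {
  Z <- rbind(Z)
  n <- nrow(Z); d <- ncol(Z)
  D <- pairwise_distances(Z)
  k <- resolve_k(spec, n)
  dk <- adaptive_bandwidth(D, k)
  lw <- kernel_weights(D, dk, spec)
  V <- cbind(1, Z)
  beta <- matrix(NA_real_, n, d + 1L)
  beta_null <- s2f <- s2n <- nlr <- numeric(n)
  for (i in seq_len(n)) {
    w <- lw$W[i, ]
    beta[i, ] <- fit_local_wls(Z, y, w, ridge_eps)
    beta_null[i] <- fit_local_null(y, w)
    lr <- neg_log_likelihood_ratio(w, y - V %*% beta[i, ], y - beta_null[i],
                                   floor = var_floor)
    s2f[i] <- lr$sigma2_full; s2n[i] <- lr$sigma2_null
    nlr[i] <- lr$neg_log_ratio
  }
  colnames(beta) <- c("beta0", paste0("beta", seq_len(d)))
  structure(list(beta = beta, beta_null = beta_null,
                 sigma2_full = s2f, sigma2_null = s2n, neg_log_ratio = nlr,
                 fitted_local = rowSums(V * beta),
                 weights = lw, spec = spec, k = k,
                 ridge_eps = ridge_eps, var_floor = var_floor),
            class = "local_fits")
}

#' Localized-regression prediction loss
#'
#' Mean over patients of the negative log-likelihood ratio comparing each
#' patient's local full model to its local intercept-only model under the
#' same kernel weights. Always <= 0; the more the latent space supports
#' locally informative linear models of the outcome, the more negative the
#' loss.
#'
#' @inheritParams fit_local_all
#' @return Scalar loss.
#' @export
prediction_loss <- function(Z, y, spec = kernel_spec(), ridge_eps = 1e-6,
                            var_floor = 1e-8) {
  Z <- rbind(Z)
  if (nrow(Z) < ncol(Z) + 2L)
    stop("need n >= d + 2 patients", call. = FALSE)
  mean(fit_local_all(Z, y, spec, ridge_eps, var_floor)$neg_log_ratio)
}

# Analytic gradient of prediction_loss w.r.t. Z (Gaussian kernel only).
#
# Per patient i (weights w_ij, S = sum_j w_ij, weighted SSEs of the full and
# null fits), the loss term is (S/2) log(SSE_f / SSE_n). Differentiation
# paths: (a) every w_ij through the scaled distance u_ij = d_ij / dk_i,
# where both d_ij and the k-th-neighbor distance dk_i depend on Z (the
# neighbor *index* is held fixed — ranking is piecewise constant); (b) the
# regressor rows z_j inside the full-fit residuals; (c) the fitted
# coefficients themselves. At the exact WLS optimum path (c) vanishes
# (envelope theorem); with the ridge jitter the optimum of the penalized
# objective is differentiated implicitly through the normal equations via a
# per-patient adjoint solve, so the gradient is exact for any ridge_eps.
prediction_loss_grad <- function(Z, y, spec = kernel_spec(),
                                 ridge_eps = 1e-6, var_floor = 1e-8) {
  if (spec$family != "gaussian")
    stop("gradient implemented for the gaussian kernel only", call. = FALSE)
  Z <- rbind(Z)
  n <- nrow(Z); d <- ncol(Z)
  D <- pairwise_distances(Z)
  k <- resolve_k(spec, n)
  bw <- adaptive_bandwidth(D, k, return_index = TRUE)
  dk <- bw$dk; kidx <- bw$idx
  U <- sweep(D, 1, dk, "/")
  W <- exp(-U^2 / (2 * spec$sigma^2))
  V <- cbind(1, Z)

  B <- matrix(NA_real_, n, d + 1L)
  Lam <- matrix(0, n, d + 1L)  # adjoints of the ridge-penalized solves
  beta0 <- numeric(n)
  for (i in seq_len(n)) {
    w <- W[i, ]
    A_i <- crossprod(V, w * V)
    if (ridge_eps > 0) diag(A_i)[-1] <- diag(A_i)[-1] + ridge_eps
    ch <- chol(A_i)
    B[i, ] <- backsolve(ch, forwardsolve(t(ch), crossprod(V, w * y)))
    if (ridge_eps > 0)
      Lam[i, ] <- backsolve(ch, forwardsolve(
        t(ch), -2 * ridge_eps * c(0, B[i, -1])))
    beta0[i] <- fit_local_null(y, w)
  }
  Fit <- V %*% t(B)              # Fit[j, i] = model i evaluated at z_j
  Ef <- t(matrix(y, n, n) - Fit) # Ef[i, j] = full-fit residual of j in model i
  En <- outer(-beta0, y, `+`)    # En[i, j] = y_j - beta0_i
  S <- rowSums(W)
  SSEf <- rowSums(W * Ef^2)
  SSEn <- rowSums(W * En^2)

  floorS <- var_floor * S
  f_floored <- SSEf < floorS
  n_floored <- SSEn < floorS
  # per-patient multipliers: cS on dS, cF on dSSE_f, cN on dSSE_n
  cS <- 0.5 * log(pmax(SSEf, floorS) / pmax(SSEn, floorS))
  cF <- S / (2 * pmax(SSEf, floorS))
  cN <- -S / (2 * pmax(SSEn, floorS))
  cF[f_floored] <- 0
  cS[f_floored] <- 0.5 * (log(floorS[f_floored] / SSEn[f_floored]) + 1)
  cS[n_floored] <- 0; cF[n_floored] <- 0; cN[n_floored] <- 0

  A <- cS + cF * Ef^2 + cN * En^2      # coefficient on each dw_ij
  Pt <- NULL
  if (ridge_eps > 0) {
    # implicit-differentiation correction: dSSE_f picks up
    # -2 eps (D beta)' dbeta = lambda' (db - dA beta) with
    # lambda = A^{-1}(-2 eps D beta); its dw_ij part is (lambda'v_j) e_ij
    Pt <- t(V %*% t(Lam))              # Pt[i, j] = lambda_i' v_j
    A <- A + cF * Pt * Ef
  }
  Bb <- A * W * (-U / spec$sigma^2)    # coefficient on each du_ij
  # path through d_ij at fixed dk_i
  H <- Bb / (dk * D)                   # dk recycles down columns = rowwise
  H[!is.finite(H)] <- 0                # diagonal / duplicate points
  diag(H) <- 0
  grad <- (rowSums(H) + colSums(H)) * Z - (H + t(H)) %*% Z
  # path through dk_i (its own distance to the fixed k-th neighbor)
  g2 <- -rowSums(Bb * U) / dk          # coefficient on d(dk_i)
  diffK <- (Z - Z[kidx, , drop = FALSE]) * (g2 / dk)
  grad <- grad + diffK
  for (i in seq_len(n))
    grad[kidx[i], ] <- grad[kidx[i], ] - diffK[i, ]
  # path through the regressor rows z_j in the full-fit residuals:
  # dSSE_f(i) includes -2 w_ij e_ij beta_i[1:d] . dz_j
  Rm <- -2 * cF * W * Ef
  grad <- grad + t(Rm) %*% B[, -1, drop = FALSE]
  if (ridge_eps > 0) {
    # dz_j part of the implicit correction:
    # w_ij (e_ij lambda_i[1:d] - (lambda_i'v_j) beta_i[1:d])
    grad <- grad + t(cF * W * Ef) %*% Lam[, -1, drop = FALSE] -
      t(cF * W * Pt) %*% B[, -1, drop = FALSE]
  }
  grad / n
}
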