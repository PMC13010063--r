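#' Principal-component baseline
#'
#' Projects the standardized predictors onto the first `n_components`
#' principal directions of the training covariance and fits the global
#' linear model on the scores. The component count defaults to the latent
#' dimension of the autoencoder so the comparison is like-for-like.
#'
#' @param X_std Standardized n x p predictor matrix.
#' @param y Length-n outcome.
#' @param n_components Number of components (default 4).
#' @return List with `scores` (n x n_components), `rotation`, and `fit`
#'   (a `global_fit`).
#' @export
pca_baseline <- function(X_std, y, n_components = 4L) {
  if (n_components > min(dim(X_std)))
    stop("`n_components` must be <= min(n, p)", call. = FALSE)
  pc <- stats::prcomp(X_std, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  list(scores = scores,
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
       fit = fit_global(scores, y))
}

#' Reconstruction-only autoencoder baseline
#'
#' Identical architecture and training procedure as the proposed model but
#' with `lambda_pred = 0`, i.e. a regular autoencoder trained purely for
#' reconstruction; the global model is then fitted on its latent space.
#' With the same seed this reduces exactly to [train()] with
#' `lambda_pred = 0`.
#'
#' @param X_std,y Standardized training data.
#' @param config A [train_config()]; its `lambda_pred` is forced to 0 and
#'   `lambda_rec` to 1.
#' @return List with `result` (a `train_result`) and `fit` (a `global_fit`
#'   on its latent space).
#' @export
plain_ae_baseline <- function(X_std, y, config = train_config()) {
  config$lambda_pred <- 0
  config$lambda_rec <- 1
  res <- train(X_std, y, config)
  list(result = res, fit = fit_global(res$Z_final, y))
}

#' Configuration for stepwise regression with interaction search
#'
#' @param screen_p_threshold Univariate screening p-value threshold
#'   (default 0.05; 0.10 and 0.157 are the other conventionally swept
#'   values).
#' @param backward_aic_min_improvement Minimum AIC decrease for a backward
#'   elimination step (default 1).
#' @param forward_aic_min_improvement Minimum AIC decrease for adding a
#'   pairwise interaction (default 2).
#' @return Object of class `stepwise_config`.
#' @export
stepwise_config <- function(screen_p_threshold = 0.05,
                            backward_aic_min_improvement = 1,
                            forward_aic_min_improvement = 2) {
  if (screen_p_threshold <= 0 || screen_p_threshold >= 1)
    stop("`screen_p_threshold` must be in (0, 1)", call. = FALSE)
  structure(list(screen_p_threshold = screen_p_threshold,
                 backward_aic_min_improvement = backward_aic_min_improvement,
                 forward_aic_min_improvement = forward_aic_min_improvement),
            class = "stepwise_config")
}

# Gaussian OLS AIC: n log(SSE/n) + 2 (#coefficients + 1 for the variance)
ols_aic <- function(X, y) {
  n <- length(y)
  if (NCOL(X) == 0 || is.null(X)) {
    sse <- sum((y - mean(y))^2)
    k <- 1L
  } else {
    fit <- stats::lm.fit(cbind(1, as.matrix(X)), y)
    sse <- sum(fit$residuals^2)
    k <- ncol(as.matrix(X)) + 1L
  }
  n * log(sse / n) + 2 * (k + 1L)
}

#' Stepwise regression with pairwise-interaction search
#'
#' Three stages on the training data: (1) univariate screen — each
#' predictor is regressed on the outcome alone and kept if its slope
#' p-value is below the threshold; (2) backward elimination on the screened
#' main effects — repeatedly drop the variable whose removal most decreases
#' the AIC, while the decrease exceeds the backward threshold; (3) forward
#' selection over all pairwise products of the surviving main effects —
#' repeatedly add the interaction with the largest AIC decrease above the
#' forward threshold. Interactions are products of the standardized
#' columns (not re-standardized); ties break toward the lowest column
#' index, so the procedure is deterministic.
#'
#' @param X_std Standardized n x p predictor matrix.
#' @param y Length-n outcome.
#' @param config A [stepwise_config()].
#' @return Object of class `stepwise_model`: `screened`, `main_effects`,
#'   `interactions` (character vectors), `aic`, `r_squared`, and `trace`
#'   (data.frame of every accepted step with AIC before/after and delta).
#' @export
stepwise_interactions <- function(X_std, y, config = stepwise_config()) {
  stopifnot(inherits(config, "stepwise_config"))
  X_std <- as.matrix(X_std)
  if (is.null(colnames(X_std))) colnames(X_std) <- paste0("x", seq_len(ncol(X_std)))
  n <- length(y)

  pvals <- apply(X_std, 2, function(x)
    summary(stats::lm(y ~ x))$coefficients[2, 4])
  screened <- colnames(X_std)[pvals < config$screen_p_threshold]
  if (length(screened) == 0) {
    warning("no predictor survives the univariate screen")
    return(structure(list(screened = character(0),
                          main_effects = character(0),
                          interactions = character(0),
                          aic = ols_aic(NULL, y), r_squared = 0,
                          trace = data.frame()), class = "stepwise_model"))
  }
  if (n <= length(screened) + 2L)
    stop("too many screened predictors for the sample size; ",
         "tighten `screen_p_threshold`", call. = FALSE)

  trace <- data.frame(step = integer(), action = character(),
                      term = character(), aic_before = numeric(),
                      aic_after = numeric(), delta = numeric())
  step_i <- 0L

  # backward elimination on main effects
  mains <- screened
  aic_cur <- ols_aic(X_std[, mains, drop = FALSE], y)
  while (length(mains) > 0L) {
    cand <- vapply(seq_along(mains), function(j)
      ols_aic(X_std[, mains[-j], drop = FALSE], y), numeric(1))
    j <- which.min(cand)  # first minimum = lowest index on ties
    improvement <- aic_cur - cand[j]
    if (improvement <= config$backward_aic_min_improvement) break
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(step = step_i, action = "drop",
                                     term = mains[j], aic_before = aic_cur,
                                     aic_after = cand[j],
                                     delta = improvement))
    mains <- mains[-j]
    aic_cur <- cand[j]
  }

  # forward selection over pairwise products of the selected main effects
  interactions <- character(0)
  M <- X_std[, mains, drop = FALSE]
  if (length(mains) >= 2L) {
    pairs <- utils::combn(mains, 2)
    pool <- apply(pairs, 2, paste, collapse = ":")
    pool_cols <- lapply(seq_len(ncol(pairs)), function(j)
      X_std[, pairs[1, j]] * X_std[, pairs[2, j]])
    names(pool_cols) <- pool
    repeat {
      remaining <- setdiff(pool, interactions)
      if (length(remaining) == 0L) break
      design_base <- cbind(M, do.call(cbind, pool_cols[interactions]))
      cand <- vapply(remaining, function(term)
        ols_aic(cbind(design_base, pool_cols[[term]]), y), numeric(1))
      j <- which.min(cand)
      improvement <- aic_cur - cand[j]
      if (improvement <= config$forward_aic_min_improvement) break
      step_i <- step_i + 1L
      trace <- rbind(trace, data.frame(step = step_i, action = "add",
                                       term = remaining[j],
                                       aic_before = aic_cur,
                                       aic_after = cand[j],
                                       delta = improvement))
      interactions <- c(interactions, remaining[j])
      aic_cur <- cand[j]
    }
  }

  int_cols <- if (length(interactions))
    do.call(cbind, lapply(strsplit(interactions, ":"), function(pr)
      X_std[, pr[1]] * X_std[, pr[2]])) else NULL
  design <- cbind(M, int_cols)
  r2 <- if (NCOL(design) > 0) {
    fit <- stats::lm.fit(cbind(1, design), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  } else 0
  structure(list(screened = screened, main_effects = mains,
                 interactions = interactions, aic = aic_cur,
                 r_squared = r2, trace = trace),
            class = "stepwise_model")
}
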