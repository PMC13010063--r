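#' Training configuration for the composite-loss autoencoder
#'
#' @param lambda_rec,lambda_pred Nonnegative weights of the reconstruction
#'   and localized-prediction loss components; their sum must be positive.
#' @param learning_rate Adam step size (default 0.0001). Training is
#'   full-batch (one Adam step per epoch), because the local kernel weights
#'   and the k-nearest-neighbor bandwidth are defined over the whole cohort;
#'   the shipped example scenarios pair full-batch updates with a larger
#'   step size (0.01).
#' @param epochs Number of full passes / Adam steps (default 300).
#' @param d Latent dimension (default 4).
#' @param hidden Encoder hidden widths (default `c(64, 16)`); the decoder
#'   mirrors the encoder.
#' @param kernel A [kernel_spec()].
#' @param ridge_eps Ridge jitter for the local Gram matrices.
#' @param var_floor Variance floor in the likelihood-ratio terms.
#' @param seed Integer seed for the weight initialization.
#' @param patience,min_delta Optional early stop on the reconstruction
#'   trace: stop when `patience` consecutive epochs improve the
#'   reconstruction loss by less than `min_delta`. `patience = NULL`
#'   (default) trains for exactly `epochs` epochs.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lambda_rec = 1, lambda_pred = 1,
                         learning_rate = 1e-4, epochs = 300L, d = 4L,
                         hidden = c(64L, 16L), kernel = kernel_spec(),
                         ridge_eps = 1e-6, var_floor = 1e-8, seed = 1L,
                         patience = NULL, min_delta = 1e-4) {
  if (lambda_rec < 0 || lambda_pred < 0 || lambda_rec + lambda_pred <= 0)
    stop("need lambda_rec, lambda_pred >= 0 with a positive sum",
         call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  structure(list(lambda_rec = lambda_rec, lambda_pred = lambda_pred,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 d = as.integer(d), hidden = as.integer(hidden),
                 kernel = kernel, ridge_eps = ridge_eps,
                 var_floor = var_floor, seed = as.integer(seed),
                 patience = patience, min_delta = min_delta),
            class = "train_config")
}

#' Composite loss of the outcome-guided autoencoder
#'
#' `lambda_rec * Loss_rec + lambda_pred * Loss_pred`, where `Loss_rec` is the
#' mean squared reconstruction error of `decode(encode(X))` and `Loss_pred`
#' is the localized-regression likelihood-ratio loss evaluated on the
#' encoded latent coordinates.
#'
#' @param X Standardized n x p predictor matrix.
#' @param y Standardized length-n outcome.
#' @param params `autoencoder_params`.
#' @param config `train_config`.
#' @return List with `total`, `rec`, `pred`.
#' @export
composite_loss <- function(X, y, params, config) {
  Z <- encode(X, params)
  rec <- reconstruction_loss(X, decode(Z, params))
  pred <- if (config$lambda_pred > 0)
    prediction_loss(Z, y, config$kernel, config$ridge_eps, config$var_floor)
  else NA_real_
  total <- config$lambda_rec * rec +
    if (config$lambda_pred > 0) config$lambda_pred * pred else 0
  list(total = total, rec = rec, pred = pred)
}

# loss + gradients w.r.t. all autoencoder parameters
composite_loss_grad <- function(X, y, params, config) {
  n <- nrow(X); p <- ncol(X)
  enc_cache <- mlp_forward(X, params$encoder)
  Z <- enc_cache$out
  dec_cache <- mlp_forward(Z, params$decoder)
  X_hat <- dec_cache$out

  rec <- mean((X - X_hat)^2)
  dXhat <- config$lambda_rec * 2 * (X_hat - X) / (n * p)
  dec_grads <- mlp_backward(dec_cache, params$decoder, dXhat)
  dZ <- dec_grads$G_in

  pred <- NA_real_
  if (config$lambda_pred > 0) {
    pred <- prediction_loss(Z, y, config$kernel, config$ridge_eps,
                            config$var_floor)
    dZ <- dZ + config$lambda_pred *
      prediction_loss_grad(Z, y, config$kernel, config$ridge_eps,
                           config$var_floor)
  }
  enc_grads <- mlp_backward(enc_cache, params$encoder, dZ)
  total <- config$lambda_rec * rec +
    if (config$lambda_pred > 0) config$lambda_pred * pred else 0
  list(total = total, rec = rec, pred = pred,
       encoder = enc_grads, decoder = dec_grads)
}

adam_init <- function(params) {
  zero_like <- function(side) list(
    mW = lapply(side$W, function(w) w * 0),
    vW = lapply(side$W, function(w) w * 0),
    mb = lapply(side$b, function(b) b * 0),
    vb = lapply(side$b, function(b) b * 0))
  list(encoder = zero_like(params$encoder),
       decoder = zero_like(params$decoder), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd_side <- function(side, g, st) {
    for (l in seq_along(side$W)) {
      st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * g$gW[[l]]
      st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * g$gW[[l]]^2
      side$W[[l]] <- side$W[[l]] -
        lr * (st$mW[[l]] / bc1) / (sqrt(st$vW[[l]] / bc2) + eps)
      st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * g$gb[[l]]
      st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * g$gb[[l]]^2
      side$b[[l]] <- side$b[[l]] -
        lr * (st$mb[[l]] / bc1) / (sqrt(st$vb[[l]] / bc2) + eps)
    }
    list(side = side, st = st)
  }
  e <- upd_side(params$encoder, grads$encoder, state$encoder)
  d <- upd_side(params$decoder, grads$decoder, state$decoder)
  params$encoder <- e$side; state$encoder <- e$st
  params$decoder <- d$side; state$decoder <- d$st
  list(params = params, state = state)
}

#' End-to-end training of the outcome-guided autoencoder
#'
#' Full-batch Adam optimization of the composite loss. Gradients of the
#' localized-prediction component flow through the kernel weights and the
#' adaptive bandwidth into the encoder, so the latent representation is
#' simultaneously shaped for reconstruction and for locally informative
#' outcome models. Deterministic given the configuration (including seed).
#'
#' @param X Standardized n x p predictor matrix.
#' @param y Standardized length-n outcome.
#' @param config A [train_config()].
#' @return Object of class `train_result`: `params`, `loss_trace`
#'   (data.frame epoch/total/rec/pred, the loss at the parameters entering
#'   each epoch), `final_loss`, `Z_final`, and the `config`.
#' @export
train <- function(X, y, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  X <- as.matrix(X)
  if (nrow(X) <= config$d + 2L)
    stop("need n > d + 2 patients", call. = FALSE)
  spec <- encoder_spec(ncol(X), config$d, config$hidden)
  params <- autoencoder_init(spec, config$seed)
  state <- adam_init(params)
  epochs <- config$epochs
  trace <- matrix(NA_real_, epochs, 3,
                  dimnames = list(NULL, c("total", "rec", "pred")))
  stall <- 0L; best_rec <- Inf; used <- epochs
  for (e in seq_len(epochs)) {
    g <- composite_loss_grad(X, y, params, config)
    if (!is.finite(g$total))
      stop(sprintf(
        "non-finite loss at epoch %d (total=%g, rec=%g, pred=%g)",
        e, g$total, g$rec, g$pred), call. = FALSE)
    trace[e, ] <- c(g$total, g$rec, g$pred)
    st <- adam_step(params, g, state, config$learning_rate)
    params <- st$params; state <- st$state
    if (!is.null(config$patience)) {
      if (g$rec < best_rec - config$min_delta) {
        best_rec <- g$rec; stall <- 0L
      } else stall <- stall + 1L
      if (stall >= config$patience) { used <- e; break }
    }
  }
  trace <- trace[seq_len(used), , drop = FALSE]
  final <- composite_loss(X, y, params, config)
  structure(list(params = params,
                 loss_trace = data.frame(epoch = seq_len(used), trace),
                 final_loss = final,
                 Z_final = encode(X, params),
                 config = config),
            class = "train_result")
}

#' Multi-seed stability study
#'
#' Re-runs the full pipeline (training, global fit, local fits, deviation
#' profile) with `n_seeds` consecutive seeds, aligns the latent dimensions
#' of every run to a reference run by maximal absolute correlation, and
#' summarizes the stability of patient deviation ranks. The representative
#' run for reporting is the one whose reconstruction loss is closest to the
#' across-seed median.
#'
#' @param X,y Standardized training data.
#' @param config Base [train_config()]; run r uses seed `config$seed + r - 1`.
#' @param n_seeds Number of runs (default 15).
#' @return Object of class `seed_study`: `runs` (list of `train_result`),
#'   `global_fits`, `deviation` (list of n x d absolute-deviation matrices
#'   in *aligned* dimension order), `alignment`, `rank_sd` (n x d matrix of
#'   per-patient rank SDs), `rank_sd_mean` (per aligned dimension),
#'   `rec_loss` / `r2` summaries and `representative` (run index).
#' @export
run_seed_study <- function(X, y, config = train_config(), n_seeds = 15L) {
  if (n_seeds < 2) stop("`n_seeds` must be >= 2", call. = FALSE)
  runs <- vector("list", n_seeds)
  for (r in seq_len(n_seeds)) {
    cfg <- config; cfg$seed <- config$seed + r - 1L
    runs[[r]] <- tryCatch(train(X, y, cfg), error = function(e) {
      warning(sprintf("seed %d failed: %s", cfg$seed, conditionMessage(e)))
      NULL
    })
  }
  ok <- !vapply(runs, is.null, logical(1))
  runs <- runs[ok]
  if (length(runs) < 2) stop("fewer than 2 runs succeeded", call. = FALSE)

  Zs <- lapply(runs, `[[`, "Z_final")
  alignment <- align_latent_dims(Zs, reference = 1L)
  global_fits <- lapply(Zs, function(Z) fit_global(Z, y))
  deviation <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    lf <- fit_local_all(Zs[[r]], y, config$kernel, config$ridge_eps,
                        config$var_floor)
    dev <- abs(sweep(lf$beta[, -1, drop = FALSE], 2,
                     global_fits[[r]]$coefficients[-1], "-"))
    # reorder to the reference run's dimension order (signs irrelevant
    # for absolute deviations)
    deviation[[r]] <- dev[, alignment$permutation[r, ], drop = FALSE]
  }
  rs <- rank_stability(deviation)
  rec <- vapply(runs, function(r) r$final_loss$rec, numeric(1))
  r2 <- vapply(global_fits, `[[`, numeric(1), "r_squared")
  representative <- which.min(abs(rec - stats::median(rec)))
  structure(list(runs = runs, global_fits = global_fits,
                 deviation = deviation, alignment = alignment,
                 rank_sd = rs$rank_sd, rank_sd_mean = rs$rank_sd_mean,
                 rec_loss = c(mean = mean(rec), sd = stats::sd(rec)),
                 r2 = c(mean = mean(r2), sd = stats::sd(r2)),
                 representative = representative),
            class = "seed_study")
}

#' Align latent dimensions across runs
#'
#' For each run, finds the permutation and sign flips of its latent columns
#' that maximize the total absolute Pearson correlation with the reference
#' run's columns (exhaustive optimal assignment; d is small). Signs are
#' chosen so aligned correlations are positive.
#'
#' @param Zs List of n x d latent matrices (same n and d).
#' @param reference Index of the reference run (default 1).
#' @return List with `permutation` (runs x d matrix: column j of the
#'   reference corresponds to column `permutation[r, j]` of run r) and
#'   `sign` (runs x d).
#' @export
align_latent_dims <- function(Zs, reference = 1L) {
  d <- ncol(Zs[[reference]])
  n <- nrow(Zs[[reference]])
  if (d > n) stop("latent dimension exceeds patient count", call. = FALSE)
  if (d > 8L) stop("exhaustive alignment supports d <= 8", call. = FALSE)
  perms <- permutations(d)
  nr <- length(Zs)
  P <- matrix(NA_integer_, nr, d)
  Sg <- matrix(NA_real_, nr, d)
  ref <- Zs[[reference]]
  for (r in seq_len(nr)) {
    C <- suppressWarnings(stats::cor(ref, Zs[[r]]))
    C[!is.finite(C)] <- 0
    scores <- apply(perms, 1, function(pm)
      sum(abs(C[cbind(seq_len(d), pm)])))
    best <- perms[which.max(scores), ]
    P[r, ] <- best
    s <- sign(C[cbind(seq_len(d), best)])
    s[s == 0] <- 1
    Sg[r, ] <- s
  }
  list(permutation = P, sign = Sg, reference = reference)
}

permutations <- function(d) {
  if (d == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(d - 1L)
  out <- matrix(0L, 0, d)
  for (i in seq_len(d)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Deviation-rank stability across runs
#'
#' Each run supplies a per-patient, per-(aligned)-dimension absolute
#' deviation `|beta_local - beta_global|`. Within each run and dimension,
#' patients are ranked (rank 1 = largest deviation); the population SD of
#' each patient's rank across runs measures how consistently the runs order
#' the patients. Lower is more stable.
#'
#' @param deviation List (one element per run) of n x d matrices of absolute
#'   deviations, with dimensions already aligned across runs.
#' @return List with `rank_sd` (n x d) and `rank_sd_mean` (per dimension,
#'   mean over patients).
#' @export
rank_stability <- function(deviation) {
  if (length(deviation) < 2) stop("need >= 2 runs", call. = FALSE)
  dims <- vapply(deviation, ncol, integer(1))
  if (length(unique(dims)) != 1)
    stop("runs disagree on the number of latent dimensions", call. = FALSE)
  n <- nrow(deviation[[1]]); d <- dims[1]; R <- length(deviation)
  ranks <- array(NA_real_, c(n, d, R))
  for (r in seq_len(R))
    for (l in seq_len(d))
      ranks[, l, r] <- rank(-deviation[[r]][, l], ties.method = "average")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  rank_sd <- matrix(NA_real_, n, d)
  for (l in seq_len(d))
    rank_sd[, l] <- apply(ranks[, l, , drop = FALSE], 1, pop_sd)
  list(rank_sd = rank_sd, rank_sd_mean = colMeans(rank_sd))
}
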