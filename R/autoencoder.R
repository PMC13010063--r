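#' Multilayer-perceptron specification
#'
#' Layer widths from input to output; a tanh activation is applied after
#' every layer except the final one, so the latent representation (encoder
#' output) and the reconstruction (decoder output) are unbounded —
#' appropriate for standardized data that lives outside \[-1, 1\].
#'
#' @param layer_widths Integer vector of at least two positive widths.
#' @return Object of class `mlp_spec`.
#' @export
mlp_spec <- function(layer_widths) {
  layer_widths <- as.integer(layer_widths)
  if (length(layer_widths) < 2L || any(layer_widths < 1L))
    stop("`layer_widths` needs >= 2 positive widths", call. = FALSE)
  structure(list(layer_widths = layer_widths), class = "mlp_spec")
}

#' Default encoder specification
#'
#' Three fully connected layers: p inputs, hidden widths 64 and 16, d latent
#' outputs, tanh after the first two layers. The decoder mirrors it.
#'
#' @param p Number of predictors.
#' @param d Latent dimension (default 4).
#' @param hidden Hidden layer widths (default `c(64, 16)`).
#' @return An `mlp_spec` for the encoder.
#' @export
encoder_spec <- function(p, d = 4L, hidden = c(64L, 16L)) {
  mlp_spec(c(p, hidden, d))
}

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
mlp_init <- function(spec) {
  w <- spec$layer_widths
  L <- length(w) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    s <- 1 / sqrt(w[l])
    W[[l]] <- matrix(stats::runif(w[l] * w[l + 1L], -s, s), w[l], w[l + 1L])
    b[[l]] <- stats::runif(w[l + 1L], -s, s)
  }
  list(W = W, b = b, spec = spec)
}

#' Initialize autoencoder parameters
#'
#' Draws encoder and decoder weights with uniform fan-in scaling from the
#' given seed. The decoder specification is the reverse of the encoder's.
#'
#' @param spec Encoder `mlp_spec` (see [encoder_spec()]).
#' @param seed Integer seed controlling the initialization.
#' @return Object of class `autoencoder_params` with elements `encoder`,
#'   `decoder` and `spec`.
#' @export
autoencoder_init <- function(spec, seed = 1L) {
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  dec_spec <- mlp_spec(rev(spec$layer_widths))
  structure(list(encoder = mlp_init(spec), decoder = mlp_init(dec_spec),
                 spec = spec),
            class = "autoencoder_params")
}

# forward pass; returns output plus per-layer inputs for backprop
mlp_forward <- function(X, params) {
  L <- length(params$W)
  inputs <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    inputs[[l]] <- H
    H <- H %*% params$W[[l]]
    H <- sweep(H, 2, params$b[[l]], "+")
    if (l < L) H <- tanh(H)
  }
  list(out = H, inputs = inputs)
}

# backward pass: G is dLoss/d(out); returns gradients and dLoss/d(input)
mlp_backward <- function(cache, params, G) {
  L <- length(params$W)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    if (l < L) {
      # inputs[[l + 1]] is the tanh output of layer l
      A <- cache$inputs[[l + 1L]]
      G <- G * (1 - A^2)
    }
    gW[[l]] <- crossprod(cache$inputs[[l]], G)
    gb[[l]] <- colSums(G)
    G <- tcrossprod(G, params$W[[l]])
  }
  list(gW = gW, gb = gb, G_in = G)
}

#' Encode patients into the latent representation
#'
#' @param X Standardized n x p matrix (or a single row as a vector).
#' @param params `autoencoder_params`.
#' @return n x d latent matrix Z.
#' @export
encode <- function(X, params) {
  stopifnot(inherits(params, "autoencoder_params"))
  X <- rbind(X)  # promote a vector to a 1-row matrix
  p_exp <- params$spec$layer_widths[1]
  if (ncol(X) != p_exp)
    stop(sprintf("encoder expects %d predictors, got %d", p_exp, ncol(X)),
         call. = FALSE)
  mlp_forward(X, params$encoder)$out
}

#' Decode latent coordinates back to predictor space
#'
#' @param Z n x d latent matrix.
#' @param params `autoencoder_params`.
#' @return n x p reconstruction.
#' @export
decode <- function(Z, params) {
  stopifnot(inherits(params, "autoencoder_params"))
  Z <- rbind(Z)
  d_exp <- utils::tail(params$spec$layer_widths, 1)
  if (ncol(Z) != d_exp)
    stop(sprintf("decoder expects %d latent dims, got %d", d_exp, ncol(Z)),
         call. = FALSE)
  mlp_forward(Z, params$decoder)$out
}

#' Mean squared reconstruction error
#'
#' Squared Frobenius norm of `X - X_hat` divided by the number of entries
#' (n * p).
#'
#' @param X Original matrix.
#' @param X_hat Reconstruction of the same shape.
#' @return Nonnegative scalar; 0 iff the reconstruction is exact.
#' @export
reconstruction_loss <- function(X, X_hat) {
  if (!identical(dim(rbind(X)), dim(rbind(X_hat))))
    stop("`X` and `X_hat` must have identical shapes", call. = FALSE)
  mean((X - X_hat)^2)
}

#' Save / load autoencoder parameters as a JSON checkpoint
#'
#' @param params `autoencoder_params`.
#' @param path Destination file.
#' @param meta Optional named list (seed, training config, ...) embedded in
#'   the checkpoint.
#' @return `path` invisibly; `load_checkpoint` returns a list with `params`
#'   and `meta`.
#' @export
save_checkpoint <- function(params, path, meta = list()) {
  stopifnot(inherits(params, "autoencoder_params"))
  flat <- function(side) list(W = lapply(side$W, as.numeric), b = side$b)
  obj <- list(
    spec = params$spec$layer_widths,
    encoder = flat(params$encoder),
    decoder = flat(params$decoder),
    meta = meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- mlp_spec(obj$spec)
  dec_spec <- mlp_spec(rev(obj$spec))
  as_mats <- function(side, spec) {
    w <- spec$layer_widths
    L <- length(w) - 1L
    W <- lapply(seq_len(L), function(l) matrix(side$W[[l]], w[l], w[l + 1L]))
    b <- lapply(seq_len(L), function(l) as.numeric(side$b[[l]]))
    list(W = W, b = b, spec = spec)
  }
  params <- structure(list(encoder = as_mats(obj$encoder, spec),
                           decoder = as_mats(obj$decoder, dec_spec),
                           spec = spec),
                      class = "autoencoder_params")
  list(params = params, meta = obj$meta)
}
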