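#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration for [generate_synthetic()]. The generator
#' emulates the data structure the diagnostic framework assumes: predictors
#' lying near a low-dimensional nonlinear manifold, an outcome linearly
#' related to the manifold coordinates for most patients, and one or more
#' planted subgroups whose local coefficients deviate from the global ones
#' along specific latent directions.
#'
#' @param n Number of patients (at least 10).
#' @param p Number of predictors (must exceed `d_true`).
#' @param d_true True manifold dimension.
#' @param mixing_nonlinearity `"none"` for a purely linear mixing of the
#'   manifold coordinates into predictor space, or `"tanh"` for an
#'   elementwise hyperbolic-tangent distortion applied after mixing.
#' @param predictor_noise_sd SD of iid Gaussian noise added to every
#'   predictor column (>= 0).
#' @param beta_global_true Length-`d_true` global coefficient vector linking
#'   the manifold coordinates to the outcome.
#' @param subgroups List of planted subgroups; each element is a list with
#'   `fraction` (share of n, fractions must sum to < 1), `dim` (target latent
#'   dimension, 1..d_true) and `delta` (additive coefficient deviation).
#' @param outcome_noise_sd SD of the outcome error (>= 0).
#' @param subgroup_shift Latent-location shift applied to subgroup members
#'   along their target dimension so each subgroup occupies a contiguous
#'   latent region; set to 0 to plant purely coefficient-based subgroups.
#' @param dim_weights Optional length-`d_true` positive scalars giving the
#'   relative amplitude of each manifold coordinate in predictor space
#'   (default all 1). Small values create low-variance manifold directions.
#' @param mixing_matrix Optional explicit p x d_true mixing matrix; by
#'   default a random matrix with iid N(0,1) entries scaled to unit column
#'   norms is drawn from the seed.
#' @param seed Integer RNG seed; the whole dataset is deterministic given the
#'   configuration.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 200, p = 30, d_true = 2,
                             mixing_nonlinearity = c("tanh", "none"),
                             predictor_noise_sd = 0.1,
                             beta_global_true = rep(1, d_true),
                             subgroups = list(),
                             outcome_noise_sd = 0.3,
                             subgroup_shift = 1.5,
                             dim_weights = rep(1, d_true),
                             mixing_matrix = NULL,
                             seed = 1L) {
  mixing_nonlinearity <- match.arg(mixing_nonlinearity)
  if (!is.numeric(n) || length(n) != 1L || n < 10)
    stop("invalid `n`: need a single patient count >= 10", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p < 1)
    stop("invalid `p`: need a single positive predictor count", call. = FALSE)
  if (!is.numeric(d_true) || length(d_true) != 1L || d_true < 1 || d_true >= p)
    stop("invalid `d_true`: need 1 <= d_true < p", call. = FALSE)
  if (predictor_noise_sd < 0)
    stop("invalid `predictor_noise_sd`: must be >= 0", call. = FALSE)
  if (outcome_noise_sd < 0)
    stop("invalid `outcome_noise_sd`: must be >= 0", call. = FALSE)
  if (length(beta_global_true) != d_true)
    stop("invalid `beta_global_true`: length must equal `d_true`", call. = FALSE)
  if (length(dim_weights) != d_true || any(dim_weights <= 0))
    stop("invalid `dim_weights`: need length-d_true positive values", call. = FALSE)
  if (!is.list(subgroups))
    stop("invalid `subgroups`: must be a list", call. = FALSE)
  for (sg in subgroups) {
    if (!all(c("fraction", "dim", "delta") %in% names(sg)))
      stop("invalid `subgroups`: each entry needs fraction, dim, delta",
           call. = FALSE)
    if (sg$fraction <= 0 || sg$dim < 1 || sg$dim > d_true)
      stop("invalid `subgroups`: fraction must be > 0 and dim in 1..d_true",
           call. = FALSE)
  }
  if (length(subgroups) &&
      sum(vapply(subgroups, `[[`, numeric(1), "fraction")) >= 1)
    stop("invalid `subgroups`: fractions must sum to < 1", call. = FALSE)
  if (!is.null(mixing_matrix) &&
      !identical(dim(mixing_matrix), c(as.integer(p), as.integer(d_true))))
    stop("invalid `mixing_matrix`: must be p x d_true", call. = FALSE)

  structure(list(n = as.integer(n), p = as.integer(p),
                 d_true = as.integer(d_true),
                 mixing_nonlinearity = mixing_nonlinearity,
                 predictor_noise_sd = predictor_noise_sd,
                 beta_global_true = as.numeric(beta_global_true),
                 subgroups = subgroups,
                 outcome_noise_sd = outcome_noise_sd,
                 subgroup_shift = subgroup_shift,
                 dim_weights = as.numeric(dim_weights),
                 mixing_matrix = mixing_matrix,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic patient cohort
#'
#' Draws manifold coordinates `u ~ N(0, I_d_true)` per patient, maps them to
#' predictor space through a fixed random mixing matrix with unit column
#' norms (optionally distorted elementwise by tanh) plus Gaussian predictor
#' noise, and produces the outcome as the latent linear predictor plus noise.
#' Subgroup members get `beta_global_true` modified by `delta` on their
#' target dimension (and, by default, a latent-location shift so the
#' subgroup is a contiguous region).
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_dataset`: list with `X_raw`
#'   (n x p, columns `x1..xp`), `y_raw`, `latent_true` (n x d_true),
#'   `subgroup_labels` (0 = background), `beta_by_patient` (n x d_true),
#'   `mixing_matrix` and the `config`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n; p <- config$p; d <- config$d_true
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(config$seed)

  M <- config$mixing_matrix
  if (is.null(M)) {
    M <- matrix(stats::rnorm(p * d), p, d)
    M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  }
  M <- sweep(M, 2, config$dim_weights, "*")

  u <- matrix(stats::rnorm(n * d), n, d)

  labels <- integer(n)
  beta <- matrix(rep(config$beta_global_true, each = n), n, d)
  if (length(config$subgroups)) {
    pool <- sample.int(n)  # random disjoint membership
    used <- 0L
    for (g in seq_along(config$subgroups)) {
      sg <- config$subgroups[[g]]
      size <- max(1L, round(sg$fraction * n))
      members <- pool[(used + 1L):(used + size)]
      used <- used + size
      labels[members] <- g
      beta[members, sg$dim] <- beta[members, sg$dim] + sg$delta
      if (config$subgroup_shift != 0) {
        dir <- if (g %% 2L == 0L) -1 else 1
        u[members, sg$dim] <- u[members, sg$dim] * 0.4 +
          dir * config$subgroup_shift
      }
    }
  }

  X <- u %*% t(M)
  if (config$mixing_nonlinearity == "tanh") X <- tanh(X)
  if (config$predictor_noise_sd > 0)
    X <- X + matrix(stats::rnorm(n * p, sd = config$predictor_noise_sd), n, p)
  colnames(X) <- paste0("x", seq_len(p))

  y <- rowSums(u * beta)
  if (config$outcome_noise_sd > 0)
    y <- y + stats::rnorm(n, sd = config$outcome_noise_sd)

  structure(list(X_raw = X, y_raw = y, latent_true = u,
                 subgroup_labels = labels, beta_by_patient = beta,
                 mixing_matrix = M, config = config),
            class = "synthetic_dataset")
}

#' Standardize predictors and outcome
#'
#' Columnwise centering/scaling of the predictor matrix and the outcome to
#' mean 0 and SD 1. When `stats` is supplied (typically computed on the
#' training rows) those statistics are applied instead of recomputing them,
#' so test data are placed on the training scale without leakage.
#'
#' @param X Numeric n x p matrix.
#' @param y Numeric length-n outcome.
#' @param stats Optional `standardization_stats` from a previous call.
#' @return List with standardized `X`, `y` and the `stats`
#'   (class `standardization_stats`: `means`, `sds` of length p + 1, the
#'   outcome last, and `computed_on`).
#' @export
standardize <- function(X, y, stats = NULL) {
  X <- as.matrix(X)
  if (is.null(stats)) {
    means <- c(colMeans(X), mean(y))
    sds <- c(apply(X, 2, stats::sd), stats::sd(y))
    bad <- which(sds == 0 | !is.finite(sds))
    if (length(bad)) {
      nm <- c(colnames(X), ".outcome")[bad[1]]
      if (is.null(nm) || is.na(nm)) nm <- paste0("column ", bad[1])
      stop("zero-variance column: ", nm, call. = FALSE)
    }
    stats <- structure(list(means = means, sds = sds, computed_on = "all"),
                       class = "standardization_stats")
  }
  p <- ncol(X)
  Xs <- sweep(sweep(X, 2, stats$means[seq_len(p)], "-"),
              2, stats$sds[seq_len(p)], "/")
  ys <- (y - stats$means[p + 1L]) / stats$sds[p + 1L]
  list(X = Xs, y = ys, stats = stats)
}

#' Deterministic train/test split
#'
#' @param n Number of patients (or a `synthetic_dataset`, whose n is used).
#' @param test_fraction Proportion in (0, 1) assigned to the test set; at
#'   least one patient always lands in each set.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
train_test_split <- function(n, test_fraction, seed = 1L) {
  if (inherits(n, "synthetic_dataset")) n <- nrow(n$X_raw)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  n <- as.integer(n)
  n_test <- min(n - 1L, max(1L, round(n * test_fraction)))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(seed)
  test <- sort(sample.int(n, n_test))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Write / read a synthetic dataset as CSV plus a JSON sidecar
#'
#' The CSV holds one header row with columns `x1..xp`, `y`, and truth columns
#' prefixed `truth_` (subgroup label, true latent coordinates, true local
#' coefficients). The sidecar records the generating configuration and seed.
#'
#' @param dataset A `synthetic_dataset`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.config.json`.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  df <- as.data.frame(dataset$X_raw)
  df$y <- dataset$y_raw
  df$truth_subgroup <- dataset$subgroup_labels
  for (l in seq_len(ncol(dataset$latent_true)))
    df[[paste0("truth_u", l)]] <- dataset$latent_true[, l]
  for (l in seq_len(ncol(dataset$beta_by_patient)))
    df[[paste0("truth_beta", l)]] <- dataset$beta_by_patient[, l]
  utils::write.csv(df, path, row.names = FALSE)
  cfg <- dataset$config
  cfg$mixing_matrix <- dataset$mixing_matrix
  jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_synthetic
#' @param path CSV path previously written by [write_synthetic()] (or any
#'   CSV with `x*` predictor columns and a `y` outcome column).
#' @return For `read_synthetic`: a list with `X_raw`, `y_raw` and any truth
#'   columns found.
#' @export
read_synthetic <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  if (!length(xcols) || !("y" %in% names(df)))
    stop("CSV must contain x1..xp predictor columns and a y column",
         call. = FALSE)
  out <- list(X_raw = as.matrix(df[xcols]), y_raw = df$y)
  if ("truth_subgroup" %in% names(df))
    out$subgroup_labels <- df$truth_subgroup
  ucols <- grep("^truth_u[0-9]+$", names(df), value = TRUE)
  if (length(ucols)) out$latent_true <- as.matrix(df[ucols])
  bcols <- grep("^truth_beta[0-9]+$", names(df), value = TRUE)
  if (length(bcols)) out$beta_by_patient <- as.matrix(df[bcols])
  out
}

# save/restore global RNG state so generators don't clobber the caller's stream
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
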