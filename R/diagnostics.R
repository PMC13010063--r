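#' Global linear model on the latent dimensions
#'
#' Ordinary least squares of the outcome on the latent coordinates with an
#' intercept, fitted once to the whole training cohort. Its coefficient
#' confidence intervals define the deviation-flag rule for the local fits.
#'
#' @param Z n x d latent matrix.
#' @param y Length-n outcome.
#' @param level Confidence level (default 0.95).
#' @return Object of class `global_fit`: `coefficients` (length d + 1),
#'   `ci_lower`, `ci_upper`, `r_squared`, `sigma`, `fitted`, `level`, `d`.
#' @export
fit_global <- function(Z, y, level = 0.95) {
  Z <- rbind(Z)
  d <- ncol(Z)
  if (nrow(Z) <= d + 1L) stop("need n > d + 1", call. = FALSE)
  df <- data.frame(y = y, Z)
  names(df) <- c("y", paste0("z", seq_len(d)))
  fit <- stats::lm(y ~ ., data = df)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient latent matrix", call. = FALSE)
  ci <- stats::confint(fit, level = level)
  sm <- summary(fit)
  structure(list(coefficients = unname(stats::coef(fit)),
                 ci_lower = unname(ci[, 1]), ci_upper = unname(ci[, 2]),
                 r_squared = sm$r.squared, sigma = sm$sigma,
                 fitted = unname(stats::fitted(fit)),
                 level = level, d = d),
            class = "global_fit")
}

#' Patient-by-dimension deviation profile
#'
#' For every patient and latent dimension, the difference between the local
#' and global coefficient, and a flag marking local coefficients that fall
#' strictly outside the global model's confidence interval (values exactly
#' on the boundary are not flagged).
#'
#' @param local_fits A `local_fits` object (see [fit_local_all()]).
#' @param global_fit A `global_fit`.
#' @return Object of class `deviation_profile`: data.frame with columns
#'   `patient`, `dim`, `beta_local`, `beta_global`, `difference`, `flag`,
#'   `sign`.
#' @export
deviation_profile <- function(local_fits, global_fit) {
  d <- global_fit$d
  if (ncol(local_fits$beta) != d + 1L)
    stop("local and global fits disagree on the latent dimension",
         call. = FALSE)
  n <- nrow(local_fits$beta)
  out <- do.call(rbind, lapply(seq_len(d), function(l) {
    bl <- local_fits$beta[, l + 1L]
    bg <- global_fit$coefficients[l + 1L]
    flag <- bl < global_fit$ci_lower[l + 1L] | bl > global_fit$ci_upper[l + 1L]
    data.frame(patient = seq_len(n), dim = rep(l, n), beta_local = bl,
               beta_global = rep(bg, n), difference = bl - bg, flag = flag,
               sign = sign(bl - bg))
  }))
  rownames(out) <- NULL
  class(out) <- c("deviation_profile", "data.frame")
  out
}

#' Collect flagged patients into subgroups
#'
#' Patients flagged on the same latent dimension with the same deviation
#' sign form one candidate subgroup; candidates with fewer than `min_size`
#' members are reported separately as unassigned flagged patients. A patient
#' can belong to subgroups on several dimensions.
#'
#' @param profile A `deviation_profile`.
#' @param min_size Minimum subgroup size to report (default 5).
#' @return Object of class `subgroup_set`: list with `subgroups` (each with
#'   `id`, `dim`, `sign`, `members`, `size`; sorted by size, largest first)
#'   and `unassigned` (data.frame patient/dim/sign).
#' @export
form_subgroups <- function(profile, min_size = 5L) {
  flagged <- profile[profile$flag, , drop = FALSE]
  subgroups <- list()
  unassigned <- flagged[0, c("patient", "dim", "sign")]
  for (l in sort(unique(flagged$dim))) {
    for (s in c(1, -1)) {
      rows <- flagged[flagged$dim == l & flagged$sign == s, , drop = FALSE]
      if (nrow(rows) == 0) next
      if (nrow(rows) >= min_size) {
        subgroups[[length(subgroups) + 1L]] <-
          list(dim = l, sign = s, members = rows$patient,
               size = nrow(rows))
      } else {
        unassigned <- rbind(unassigned, rows[, c("patient", "dim", "sign")])
      }
    }
  }
  if (length(subgroups)) {
    ord <- order(-vapply(subgroups, `[[`, integer(1), "size"))
    subgroups <- subgroups[ord]
    for (i in seq_along(subgroups)) subgroups[[i]]$id <- i
  }
  structure(list(subgroups = subgroups, unassigned = unassigned,
                 min_size = min_size),
            class = "subgroup_set")
}

#' Correlations between latent dimensions and original predictors
#'
#' Used to label latent dimensions by their strongest predictor
#' associations.
#'
#' @param Z n x d latent matrix.
#' @param X_std Standardized n x p predictor matrix.
#' @param m How many top predictors to list per dimension (default 5).
#' @return Object of class `latent_correlation`: `correlation` (d x p),
#'   `top` (list per dimension of named correlation vectors, decreasing
#'   absolute value), `labels` (compact per-dimension strings).
#' @export
latent_correlation <- function(Z, X_std, m = 5L) {
  Z <- rbind(Z)
  zv <- apply(Z, 2, stats::sd) == 0
  if (any(zv))
    warning("zero-variance latent dimension(s) ",
            paste(which(zv), collapse = ", "), "; correlations set to 0")
  C <- suppressWarnings(stats::cor(Z, X_std))
  C[!is.finite(C)] <- 0
  if (is.null(colnames(C))) colnames(C) <- paste0("x", seq_len(ncol(C)))
  top <- lapply(seq_len(nrow(C)), function(l) {
    v <- C[l, ]
    v[order(-abs(v))][seq_len(min(m, length(v)))]
  })
  labels <- vapply(top, function(v)
    paste(sprintf("%s(%.2f)", names(v), v), collapse = ", "), character(1))
  structure(list(correlation = C, top = top, labels = labels, m = m),
            class = "latent_correlation")
}

#' Z-score profile of a subgroup
#'
#' Mean standardized value of every original predictor among the subgroup
#' members. Because predictors are standardized on the training cohort, the
#' cohort-wide profile is the zero vector, so departures from zero show
#' which characteristics are prominent or diminished in the subgroup.
#'
#' @param X_std Standardized n x p predictor matrix (training
#'   standardization).
#' @param members Integer vector of member row indices (nonempty).
#' @param clusters Optional integer vector of length p assigning predictors
#'   to clusters (see [cluster_predictors()]); when given, a cluster-level
#'   profile (mean over member predictors) is returned alongside.
#' @return List with `profile` (length p, named) and optionally
#'   `cluster_profile`.
#' @export
zscore_profile <- function(X_std, members, clusters = NULL) {
  if (length(members) == 0) stop("empty subgroup", call. = FALSE)
  prof <- colMeans(X_std[members, , drop = FALSE])
  if (is.null(names(prof))) names(prof) <- paste0("x", seq_along(prof))
  out <- list(profile = prof)
  if (!is.null(clusters))
    out$cluster_profile <- tapply(prof, clusters, mean)
  out
}

#' Group predictors by hierarchical clustering of their correlations
#'
#' Agglomerative clustering (average linkage) with distance
#' `1 - |Pearson correlation|`, cut at `n_clusters`. Purely an
#' interpretation aid for summarizing subgroup profiles; it plays no role in
#' subgroup identification.
#'
#' @param X_std Standardized n x p predictor matrix.
#' @param n_clusters Number of clusters (default 21, capped at p).
#' @return Integer vector of length p with cluster memberships (named by
#'   predictor).
#' @export
cluster_predictors <- function(X_std, n_clusters = 21L) {
  p <- ncol(X_std)
  if (p < n_clusters)
    stop("`n_clusters` must be <= number of predictors", call. = FALSE)
  sds <- apply(X_std, 2, stats::sd)
  if (any(sds == 0))
    stop("constant predictor column(s): ",
         paste(which(sds == 0), collapse = ", "), call. = FALSE)
  D <- stats::as.dist(1 - abs(stats::cor(X_std)))
  hc <- stats::hclust(D, method = "average")
  stats::cutree(hc, k = n_clusters)
}

#' Interaction analysis for a subgroup in the original predictor space
#'
#' For each tested predictor x, fits `y ~ x + g + x:g` where g indicates
#' subgroup membership, and reports the interaction coefficient, its
#' standard error, the raw two-sided p-value and a Benjamini-Hochberg
#' adjusted p-value across the tested predictors. A significant interaction
#' confirms that the predictor-outcome relationship differs for the
#' subgroup.
#'
#' @param X_std Standardized n x p predictor matrix.
#' @param y Length-n outcome.
#' @param members Member row indices (nonempty, proper subset of patients).
#' @param predictors Column names or indices to test (e.g. the top
#'   predictors from [latent_correlation()]).
#' @return data.frame with `predictor`, `estimate`, `se`, `p_value`,
#'   `p_adj`; predictors whose interaction column is collinear are skipped
#'   with a warning.
#' @export
interaction_analysis <- function(X_std, y, members, predictors) {
  n <- nrow(X_std)
  if (length(members) == 0) stop("empty subgroup", call. = FALSE)
  g <- as.numeric(seq_len(n) %in% members)
  if (stats::var(g) == 0)
    stop("subgroup indicator is constant (subgroup is empty or everyone)",
         call. = FALSE)
  if (is.numeric(predictors) && is.null(colnames(X_std)))
    colnames(X_std) <- paste0("x", seq_len(ncol(X_std)))
  if (is.numeric(predictors)) predictors <- colnames(X_std)[predictors]
  rows <- lapply(predictors, function(nm) {
    x <- X_std[, nm]
    fit <- stats::lm(y ~ x * g)
    cf <- summary(fit)$coefficients
    if (!("x:g" %in% rownames(cf)) || any(is.na(stats::coef(fit)))) {
      warning("skipping collinear interaction for predictor ", nm)
      return(NULL)
    }
    data.frame(predictor = nm, estimate = cf["x:g", 1], se = cf["x:g", 2],
               p_value = cf["x:g", 4])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(predictor = character(), estimate = numeric(),
                      se = numeric(), p_value = numeric(),
                      p_adj = numeric()))
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' RMSE contrast: global versus local models, inside versus outside a
#' subgroup
#'
#' Quantifies how much each patient's own local model improves on the
#' global model, separately for subgroup members and the rest of the
#' cohort. A markedly larger inside improvement confirms that the subgroup
#' genuinely benefits from personalized models.
#'
#' @param y Length-n outcome.
#' @param global_fitted Global-model fitted values.
#' @param local_fitted Each patient's own local model evaluated at their own
#'   latent point (`fitted_local` from [fit_local_all()]).
#' @param members Subgroup member indices (nonempty proper subset).
#' @return List with `inside` / `outside` (each: `rmse_global`,
#'   `rmse_local`, `improvement`, `n`).
#' @export
rmse_contrast <- function(y, global_fitted, local_fitted, members) {
  n <- length(y)
  inside <- seq_len(n) %in% members
  if (!any(inside) || all(inside))
    stop("subgroup must be a nonempty proper subset", call. = FALSE)
  rmse <- function(e) sqrt(mean(e^2))
  part <- function(idx) {
    rg <- rmse(y[idx] - global_fitted[idx])
    rl <- rmse(y[idx] - local_fitted[idx])
    list(rmse_global = rg, rmse_local = rl, improvement = rg - rl,
         n = sum(idx))
  }
  list(inside = part(inside), outside = part(!inside))
}

#' Project test patients into the trained latent space
#'
#' Test rows (standardized with the training statistics) are encoded with
#' the trained parameters; each test patient's local model is then fitted
#' using the *training* patients as the weighted neighborhood, with the
#' adaptive bandwidth taken from the training neighbors. Flags use the
#' training global fit's confidence intervals, and flagged test patients
#' are assigned to an existing subgroup when they deviate on its dimension
#' with its sign.
#'
#' @param X_test_std Test predictor matrix on the training scale (possibly
#'   zero rows).
#' @param params Trained `autoencoder_params`.
#' @param train_Z,train_y Training latent matrix and outcome.
#' @param global_fit Training `global_fit`.
#' @param spec [kernel_spec()] used in training.
#' @param subgroups Optional `subgroup_set` from the training cohort.
#' @param ridge_eps Ridge jitter for the local fits.
#' @return List with `Z_test`, `profile` (a `deviation_profile` over test
#'   patients), `beta` (test-local coefficients) and `assignment` (list per
#'   test patient of matching subgroup ids, when `subgroups` is given).
#' @export
project_test <- function(X_test_std, params, train_Z, train_y, global_fit,
                         spec = kernel_spec(), subgroups = NULL,
                         ridge_eps = 1e-6) {
  n_tr <- nrow(train_Z)
  d <- ncol(train_Z)
  if (NROW(X_test_std) == 0) {
    prof <- deviation_profile(
      structure(list(beta = matrix(numeric(0), 0, d + 1L)),
                class = "local_fits"), global_fit)
    return(list(Z_test = matrix(numeric(0), 0, d), profile = prof,
                beta = matrix(numeric(0), 0, d + 1L), assignment = list()))
  }
  Z_test <- encode(X_test_std, params)
  k <- resolve_k(spec, n_tr + 1L)
  k <- min(k, n_tr)
  n_te <- nrow(Z_test)
  beta <- matrix(NA_real_, n_te, d + 1L)
  for (i in seq_len(n_te)) {
    dist_i <- sqrt(colSums((t(train_Z) - Z_test[i, ])^2))
    dk <- sort(dist_i)[k]
    if (dk == 0) dk <- max(sort(dist_i)[k + 1L], .Machine$double.eps)
    w <- switch(spec$family,
      gaussian = exp(-(dist_i / dk)^2 / (2 * spec$sigma^2)),
      tricube = pmax(1 - (dist_i / dk)^3, 0)^3)
    beta[i, ] <- fit_local_wls(train_Z, train_y, w, ridge_eps)
  }
  colnames(beta) <- c("beta0", paste0("beta", seq_len(d)))
  prof <- deviation_profile(structure(list(beta = beta),
                                      class = "local_fits"), global_fit)
  assignment <- list()
  if (!is.null(subgroups)) {
    assignment <- lapply(seq_len(n_te), function(i) {
      rows <- prof[prof$patient == i & prof$flag, , drop = FALSE]
      ids <- integer(0)
      for (sg in subgroups$subgroups)
        if (any(rows$dim == sg$dim & rows$sign == sg$sign))
          ids <- c(ids, sg$id)
      ids
    })
  }
  list(Z_test = Z_test, profile = prof, beta = beta,
       assignment = assignment)
}
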