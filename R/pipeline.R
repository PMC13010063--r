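#' Shipped synthetic study scenarios
#'
#' Two reference configurations used throughout the documentation and
#' tests:
#' \describe{
#'   \item{`"subgroup"`}{200 patients, 30 predictors on a 2-dimensional
#'     tanh-distorted manifold, one planted subgroup of 30 patients whose
#'     coefficient on the second manifold direction is shifted by -1.5,
#'     outcome noise SD 0.3. Exercises subgroup detection and the RMSE
#'     contrast.}
#'   \item{`"low_variance"`}{The outcome depends almost entirely on a
#'     low-amplitude manifold direction that contributes little predictor
#'     variance, so variance-driven reductions (PCA, reconstruction-only
#'     autoencoder) discard the signal while the composite loss can retain
#'     it. Exercises the benchmark ordering and rank stability.}
#' }
#'
#' @param name Scenario name.
#' @param seed Data seed.
#' @return A [synthetic_config()].
#' @export
scenario_config <- function(name = c("subgroup", "low_variance"),
                            seed = 1L) {
  name <- match.arg(name)
  switch(name,
    subgroup = synthetic_config(
      n = 200, p = 30, d_true = 2, mixing_nonlinearity = "tanh",
      predictor_noise_sd = 0.1, beta_global_true = c(1, 1),
      subgroups = list(list(fraction = 0.15, dim = 2, delta = -1.5)),
      outcome_noise_sd = 0.3, subgroup_shift = 1.5, seed = seed),
    low_variance = synthetic_config(
      n = 150, p = 30, d_true = 2, mixing_nonlinearity = "none",
      predictor_noise_sd = 0.5, beta_global_true = c(0.2, 1),
      subgroups = list(list(fraction = 0.15, dim = 2, delta = -1.5)),
      outcome_noise_sd = 0.2, subgroup_shift = 1.5,
      dim_weights = c(3, 0.4), seed = seed))
}

#' Training configuration used by the shipped scenarios
#'
#' Latent dimension 2 with a compact encoder, Gaussian kernel with the
#' adaptive k-nearest-neighbor bandwidth, and full-batch Adam with step
#' size 0.01 for 300 epochs. The prediction-loss weight defaults to 1e-4:
#' the likelihood-ratio term and its gradient are several orders of
#' magnitude larger than the reconstruction term, and stronger weighting
#' makes the encoder embed the outcome itself into the latent space
#' (including its noise), which linearizes away exactly the local
#' heterogeneity the diagnostic is meant to reveal. The default keeps the
#' outcome guidance on the scale of the reconstruction gradient.
#'
#' @param seed Initialization seed.
#' @param epochs Number of epochs (default 300).
#' @param lambda_pred Weight of the prediction loss (default 1e-4).
#' @return A [train_config()].
#' @export
scenario_train_config <- function(seed = 1L, epochs = 300L,
                                  lambda_pred = 1e-4) {
  train_config(lambda_rec = 1, lambda_pred = lambda_pred,
               learning_rate = 0.01, epochs = epochs, d = 2L,
               hidden = c(32L, 8L), kernel = kernel_spec(sigma = 1),
               seed = seed)
}

#' Run the full diagnostic analysis
#'
#' Orchestrates the pipeline: standardization, end-to-end training of the
#' outcome-guided autoencoder, global latent fit, patient-specific local
#' fits, deviation profile, subgroup formation, subgroup characterization
#' (Z-score profiles, latent-predictor correlations, interaction analyses,
#' RMSE contrasts), optional test-set projection, and optional benchmarks.
#'
#' @param X Raw n x p predictor matrix (training cohort).
#' @param y Raw length-n outcome.
#' @param config A [train_config()].
#' @param X_test,y_test Optional raw test data, standardized with the
#'   training statistics.
#' @param ci_level Confidence level of the global fit (default 0.95).
#' @param min_size Minimum subgroup size (default 5).
#' @param n_clusters Predictor clusters for profile summaries (default
#'   `min(21, p)`).
#' @param m_top Predictors tested in each subgroup's interaction analysis
#'   (default 5).
#' @param benchmarks Run the PCA / reconstruction-only / stepwise
#'   benchmarks (default `FALSE`).
#' @return Object of class `latentlocal_analysis` collecting every stage's
#'   result.
#' @export
run_analysis <- function(X, y, config = train_config(),
                         X_test = NULL, y_test = NULL,
                         ci_level = 0.95, min_size = 5L,
                         n_clusters = NULL, m_top = 5L,
                         benchmarks = FALSE) {
  std <- standardize(X, y)
  res <- train(std$X, std$y, config)
  Z <- res$Z_final
  gfit <- fit_global(Z, std$y, level = ci_level)
  lfits <- fit_local_all(Z, std$y, config$kernel, config$ridge_eps,
                         config$var_floor)
  profile <- deviation_profile(lfits, gfit)
  sgs <- form_subgroups(profile, min_size = min_size)
  lcor <- latent_correlation(Z, std$X, m = m_top)
  if (is.null(n_clusters)) n_clusters <- min(21L, ncol(std$X))
  clusters <- cluster_predictors(std$X, n_clusters)

  characterization <- lapply(sgs$subgroups, function(sg) {
    top <- names(lcor$top[[sg$dim]])
    list(id = sg$id, dim = sg$dim, sign = sg$sign, size = sg$size,
         zscore = zscore_profile(std$X, sg$members, clusters),
         interactions = interaction_analysis(std$X, std$y, sg$members, top),
         rmse = rmse_contrast(std$y, gfit$fitted, lfits$fitted_local,
                              sg$members))
  })

  test <- NULL
  if (!is.null(X_test)) {
    tstd <- standardize(X_test, if (is.null(y_test))
      rep(0, NROW(X_test)) else y_test, stats = std$stats)
    test <- project_test(tstd$X, res$params, Z, std$y, gfit,
                         spec = config$kernel, subgroups = sgs,
                         ridge_eps = config$ridge_eps)
    test$y_std <- if (is.null(y_test)) NULL else tstd$y
  }

  bench <- NULL
  if (benchmarks) {
    bench <- list(
      pca = pca_baseline(std$X, std$y, n_components = config$d),
      plain_ae = plain_ae_baseline(std$X, std$y, config),
      stepwise = stepwise_interactions(std$X, std$y))
  }

  structure(list(standardization = std$stats, train = res, global = gfit,
                 local = lfits, profile = profile, subgroups = sgs,
                 latent_correlation = lcor, clusters = clusters,
                 characterization = characterization, test = test,
                 benchmarks = bench, config = config),
            class = "latentlocal_analysis")
}

#' @export
print.latentlocal_analysis <- function(x, ...) {
  cat("Latent-space global-vs-local regression diagnostic\n")
  cat(sprintf("  patients: %d, predictors: %d, latent dims: %d\n",
              nrow(x$train$Z_final),
              x$train$params$spec$layer_widths[1], x$global$d))
  cat(sprintf("  final reconstruction loss: %.3f\n", x$train$final_loss$rec))
  cat(sprintf("  global latent model R^2: %.3f\n", x$global$r_squared))
  cat(sprintf("  flagged patient-dimension pairs: %d\n", sum(x$profile$flag)))
  if (length(x$subgroups$subgroups)) {
    for (sg in x$subgroups$subgroups)
      cat(sprintf("  subgroup %d: n=%d, latent dim %d, sign %+d\n",
                  sg$id, sg$size, sg$dim, sg$sign))
  } else cat("  no subgroup of the minimum size detected\n")
  invisible(x)
}

#' Write the main analysis tables to an output directory
#'
#' Emits the deviation table, local coefficients, latent coordinates,
#' loss trace, subgroup report (JSON), characterization tables, and a run
#' manifest listing every file with the configuration echo.
#'
#' @param analysis A `latentlocal_analysis`.
#' @param dir Output directory (created if missing).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put_csv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  put_csv(analysis$profile, "deviation_table.csv")
  lb <- as.data.frame(analysis$local$beta)
  lb$patient <- seq_len(nrow(lb))
  lb$sigma2_full <- analysis$local$sigma2_full
  lb$sigma2_null <- analysis$local$sigma2_null
  lb$neg_log_ratio <- analysis$local$neg_log_ratio
  put_csv(lb, "local_coefficients.csv")
  Zdf <- as.data.frame(analysis$train$Z_final)
  names(Zdf) <- paste0("z", seq_len(ncol(Zdf)))
  Zdf <- cbind(patient = seq_len(nrow(Zdf)), Zdf)
  put_csv(Zdf, "latent_coordinates.csv")
  put_csv(analysis$train$loss_trace, "loss_trace.csv")

  sg_path <- file.path(dir, "subgroups.json")
  jsonlite::write_json(list(
    subgroups = analysis$subgroups$subgroups,
    unassigned = analysis$subgroups$unassigned,
    characterization = lapply(analysis$characterization, function(ch)
      list(id = ch$id, dim = ch$dim, sign = ch$sign, size = ch$size,
           rmse = ch$rmse, interactions = ch$interactions,
           zscore_top = sort(ch$zscore$profile,
                             decreasing = TRUE)[1:min(10, length(ch$zscore$profile))]))),
    sg_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, sg_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("latentlocal")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = analysis$config$seed,
    config = unclass(analysis$config[setdiff(names(analysis$config),
                                             "kernel")]),
    kernel = unclass(analysis$config$kernel),
    files = basename(files))
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, man_path)
  invisible(files)
}

# ---- thin command-line surface (inst/cli/latentlocal.R wraps this) ----

cli_usage <- function() {
  cat("usage: latentlocal.R <simulate|run|seed-study> [options]\n",
      "  simulate  --scenario subgroup|low_variance --seed S --out FILE.csv\n",
      "  run       --data FILE.csv --seed S --epochs E --out DIR\n",
      "  seed-study --data FILE.csv --seed S --n-seeds K --epochs E --out DIR\n",
      sep = "")
}

cli_opt <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 0) return(default)
  if (i[1] == length(args)) stop("missing value for ", flag, call. = FALSE)
  args[i[1] + 1L]
}

# returns an exit code; kept side-effect-light for in-process testing
cli_main <- function(args) {
  if (length(args) == 0) { cli_usage(); return(1L) }
  cmd <- args[1]; rest <- args[-1]
  seed <- as.integer(cli_opt(rest, "--seed", "1"))
  tryCatch({
    if (cmd == "simulate") {
      scen <- cli_opt(rest, "--scenario", "subgroup")
      out <- cli_opt(rest, "--out")
      if (is.null(out)) stop("simulate needs --out", call. = FALSE)
      ds <- generate_synthetic(scenario_config(scen, seed = seed))
      write_synthetic(ds, out)
      message("wrote ", out)
      0L
    } else if (cmd == "run") {
      data <- cli_opt(rest, "--data")
      out <- cli_opt(rest, "--out", "latentlocal_run")
      if (is.null(data)) stop("run needs --data", call. = FALSE)
      epochs <- as.integer(cli_opt(rest, "--epochs", "300"))
      ds <- read_synthetic(data)
      an <- run_analysis(ds$X_raw, ds$y_raw,
                         scenario_train_config(seed = seed,
                                               epochs = epochs))
      write_analysis(an, out)
      print(an)
      0L
    } else if (cmd == "seed-study") {
      data <- cli_opt(rest, "--data")
      if (is.null(data)) stop("seed-study needs --data", call. = FALSE)
      out <- cli_opt(rest, "--out", "latentlocal_study")
      epochs <- as.integer(cli_opt(rest, "--epochs", "300"))
      n_seeds <- as.integer(cli_opt(rest, "--n-seeds", "15"))
      ds <- read_synthetic(data)
      std <- standardize(ds$X_raw, ds$y_raw)
      study <- run_seed_study(std$X, std$y,
                              scenario_train_config(seed = seed,
                                                    epochs = epochs),
                              n_seeds = n_seeds)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(list(
        n_runs = length(study$runs),
        rec_loss = as.list(study$rec_loss),
        r2 = as.list(study$r2),
        rank_sd_mean = study$rank_sd_mean,
        representative = study$representative),
        file.path(out, "seed_study.json"), auto_unbox = TRUE, digits = NA)
      message("wrote ", file.path(out, "seed_study.json"))
      0L
    } else {
      cli_usage()
      1L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
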