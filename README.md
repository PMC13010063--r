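# latentlocal

**When is one regression model enough for every patient?** `latentlocal` is
a diagnostic toolkit for contrasting a *global* linear regression model with
*patient-specific (local)* regression models, for cohorts where the number
of predictors is large relative to the number of patients (e.g. ~200
patients, ~76 clinical measurements, one continuous outcome). Localizing
directly in such a predictor space fails — distances become meaningless —
so the package learns a low-dimensional latent representation
`Z = f(X) ∈ R^{n×d}` with an autoencoder trained end-to-end on a composite
loss:

```
Loss = λ_rec · ‖X − g(f(X))‖²_F / (n·p)                    (reconstruction)
     + λ_pred · mean_i  −log [ L(β̂_i | Z) / L(β̂_0,i | Z) ]  (local prediction)
```

For each patient `i`, `β̂_i` minimizes the kernel-weighted sum of squares
`Σ_j w_ij (y_j − β0 − Σ_l β_l z_jl)²` with Gaussian weights
`w_ij = exp(−(‖z_i−z_j‖ / d_k(z_i))² / 2σ²)` and an adaptive bandwidth
`d_k(z_i)` equal to the distance to the k-th nearest neighbor; `β̂_0,i` is
the weighted intercept-only fit under the same weights. The likelihood
ratio (weighted Gaussian, plug-in variances) rewards latent spaces in which
the outcome is *locally* linearly predictable. All gradients — through the
kernel weights, the adaptive bandwidth, and the weighted least-squares
solves — are computed analytically, and verified against finite differences
in the test suite.

After training, the package fits one global OLS on the latent dimensions,
flags patients whose local coefficient falls outside the global 95%
confidence interval, collects same-dimension/same-sign flags into
subgroups, and characterizes them in the original predictor space (Z-score
profiles, predictor clustering, interaction regressions, global-vs-local
RMSE contrasts). A multi-seed study quantifies the stability of
deviation-based patient rankings across random initializations, and three
benchmarks (principal components, a reconstruction-only autoencoder, and
stepwise regression with AIC-guided pairwise-interaction search) put the
learned latent space in context. A synthetic-cohort generator with planted
coefficient-deviating subgroups makes every stage testable without any
clinical data.

## Worked example

```r
library(latentlocal)

ds  <- generate_synthetic(scenario_config("subgroup", seed = 101))
cfg <- scenario_train_config(seed = 1, epochs = 300)
an  <- run_analysis(ds$X_raw, ds$y_raw, cfg)
an
#> Latent-space global-vs-local regression diagnostic
#>   patients: 200, predictors: 30, latent dims: 2
#>   final reconstruction loss: 0.212
#>   global latent model R^2: 0.715
#>   flagged patient-dimension pairs: 166
#>   subgroup 1: n=105, latent dim 1, sign +1
#>   subgroup 2: n=60, latent dim 1, sign -1
```

The scenario plants a subgroup of 30 patients (15% of the cohort) whose
coefficient on one manifold direction is shifted by −1.5. The printout
shows the two-regime signature this creates: the deviating patients are
flagged with negative sign on the outcome-associated latent dimension
(subgroup 2 contains them plus a halo of neighbors), while the planted
deviation biases the global coefficient enough that much of the background
is flagged with the opposite sign on the same dimension (subgroup 1 — see
the methods vignette on reading such complementary subgroup pairs). The
RMSE contrast confirms that the planted patients are the ones who benefit
from personalized models; with the simulation truth in hand:

```r
ys <- (ds$y_raw - an$standardization$means[31]) / an$standardization$sds[31]
rc <- rmse_contrast(ys, an$global$fitted, an$local$fitted_local,
                    members = which(ds$subgroup_labels == 1))
rc$inside$improvement    # global -> local RMSE gain for planted patients
#> [1] 0.138
rc$outside$improvement   # gain for everyone else
#> [1] 0.014
```

`run_seed_study()` repeats training over consecutive seeds, aligns latent
dimensions across runs by maximal absolute correlation, and reports the
per-patient deviation-rank standard deviation; `write_analysis()` exports
the deviation table, local coefficients, latent coordinates, subgroup
report and a run manifest; `pca_baseline()`, `plain_ae_baseline()` and
`stepwise_interactions()` provide the comparison methods.

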