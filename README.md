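# vada

Deep generative modeling of longitudinal data: joint outcome prediction,
subject clustering and representation learning in one model.

## The problem

Balanced longitudinal studies observe N subjects at L occasions on P
mixed-type features `x_nl` and an outcome `y_nl`. Classical marginal
models fitted by generalized estimating equations (GEE) handle the
within-subject correlation through a "working" assumption
(independence, AR-1, exchangeable), model only linear covariate
effects, and struggle with high-dimensional features. Subjects often
also come from latent subgroups that the analysis should recover.

`vada` fits a variational deep generative model that addresses all
three tasks at once. Its generative process draws, per subject, a
cluster label `c ~ Cat(π)`; latent representations
`z_l ~ N(μ_c, diag σ²_c)`; features from a decoder network applied to
each `z_l`; latent *pure outcomes* from a cluster-specific linear
marginal model `u_l ~ N(β_{c0} + z_l'β_c, σ²_{u,c})`; and the observed
outcome vector from a second decoder applied to the whole vector `u` —
which couples the repeated measurements without any working correlation
assumption. Inference is stochastic variational (mean-field encoders,
reparameterized Monte-Carlo gradients, analytic Kullback–Leibler term);
the cluster posterior is a Monte-Carlo average of the closed-form
responsibilities `h(u, Z, k) ∝ π_k p(u|Z,k) p(Z|k)`.

The package also implements the baseline stack used for comparison —
VaDE and VAE auto-encoders over i.i.d. observations, Gaussian-mixture
clustering with per-subject probability merging, PCA projection, and
cluster-specific marginal models solved by a GEE fitter written here
(independence/AR-1/exchangeable, identity and logit links) — plus a
synthetic benchmark generator with four generating regimes and ground
truth labels, and evaluation metrics (MSE, adjusted Rand index,
classification error rate).

## Worked example

Generate a benchmark dataset (three latent clusters, per-cluster linear
outcome model),
fit the model, and evaluate held-out prediction and clustering:

```r
library(vada)

gen <- generate_scenario(scenario_config("00", n_subjects = 2500, seed = 1))
sp  <- split_subjects(gen$data, ratio = 0.8, seed = 1)   # 2000 train / 500 test

fit <- vada(sp$train, D = 10, K = 3, epochs = 500, seed = 1)
fit
#> <vada_fit> D=10 K=3; trained 500 epochs; final elbo -572.6236

tidy(fit)
#> # A tibble: 3 × 6
#>   cluster    pi  beta0 sigma2_u mu_norm beta_norm
#>     <int> <dbl>  <dbl>    <dbl>   <dbl>     <dbl>
#> 1       1 0.348 0.666    0.0559    2.47     0.635
#> 2       2 0.338 0.509    0.0611    2.73     0.805
#> 3       3 0.314 0.0951   0.0452    2.79     0.764

pred  <- predict(fit, sp$test, M = 100, seed = 1)
y_std <- standardize(sp$test, fit$stats)$data$y   # held-out outcomes, training scale

mse(y_std, pred$y_hat)
#> [1] 0.0621828
ari(sp$test$truth$c_true, pred$labels_yx)   # complete-data clustering rule
#> [1] 1
ari(sp$test$truth$c_true, pred$labels_x)    # feature-only clustering rule
#> [1] 1
```

Held-out mean squared error is reported on the standardized outcome
scale, so it is directly comparable to the irreducible noise variance
the generator reports (`gen$gen$noise_var_std`, about 0.038 here); an
adjusted Rand index of 1 means the generating clusters are recovered
exactly. A GEE baseline for the same data:

```r
base <- fit_baseline(sp$train, method = "gmm-mm", K = 3,
                     working = "exchangeable", seed = 1)
mse(y_std, predict(base, sp$test)$y_hat)
#> [1] 0.0397863
```

On this linear, uncoupled scenario the GEE baseline sits essentially at
the noise floor and the deep model comes close behind — matching the
benchmark's qualitative ordering for data without within-subject
coupling.

`autoplot(fit)` shows the training objective components;
`plot_latent(fit, sp$test)` shows the latent representations colored by
cluster. A command-line wrapper for simulate/train/predict/cluster
lives at `inst/cli/vada.R`.

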