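# Memoized full-scale benchmark runs shared by the acceptance tests.
# Each cell: generate at benchmark size, split 4/1, fit (D = 10, K = 3,
# desk-scale 400-epoch protocol), evaluate held-out MSE and both
# clustering rules, over seeds 1:3.

.bench_env <- new.env(parent = emptyenv())

bench_cell <- function(scenario, s, epochs = 400L) {
  key <- paste0("v", scenario, "_", s)
  if (!is.null(.bench_env[[key]])) return(.bench_env[[key]])
  gen <- generate_scenario(scenario_config(scenario, seed = s))
  sp <- split_subjects(gen$data, ratio = 0.8, seed = s)
  fit <- vada(sp$train, D = 10L, K = 3L, epochs = epochs, seed = s)
  y_std <- standardize(sp$test, fit$stats)$data$y
  pred <- predict_outcomes(fit, sp$test, M = 100L, seed = s)
  out <- list(mse = mse(y_std, pred$y_hat),
              ari_yx = ari(sp$test$truth$c_true, pred$labels_yx),
              ari_x = ari(sp$test$truth$c_true, pred$labels_x),
              floor = gen$gen$noise_var_std)
  .bench_env[[key]] <- out
  out
}

bench_gmm_cell <- function(scenario, s) {
  key <- paste0("g", scenario, "_", s)
  if (!is.null(.bench_env[[key]])) return(.bench_env[[key]])
  gen <- generate_scenario(scenario_config(scenario, seed = s))
  sp <- split_subjects(gen$data, ratio = 0.8, seed = s)
  fit <- fit_baseline(sp$train, method = "gmm-mm", K = 3L,
                      working = "exchangeable", seed = s)
  y_std <- standardize(sp$test, fit$stats)$data$y
  out <- mse(y_std, predict(fit, sp$test)$y_hat)
  .bench_env[[key]] <- out
  out
}

bench_mean <- function(scenario, what, seeds = 1:3) {
  mean(vapply(seeds, function(s) bench_cell(scenario, s)[[what]], 0))
}
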