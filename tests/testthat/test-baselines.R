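test_that("subject-level probability merging: arithmetic, oracle, row-order
           invariance", {
  probs <- matrix(c(0.6, 0.4, 0.1, 0.9), 2, 2, byrow = TRUE)
  expect_equal(merge_subject_clusters(probs, c("a", "a")), 2L)
  # L = 1 reduces to per-observation argmax
  p1 <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_equal(merge_subject_clusters(p1, c("a", "b")), c(1L, 2L))

  set.seed(4)
  N <- 20L; L <- 3L; K <- 4L
  probs <- matrix(runif(N * L * K), N * L, K)
  probs <- probs / rowSums(probs)
  ids <- rep(paste0("s", seq_len(N)), each = L)
  got <- merge_subject_clusters(probs, ids)
  want <- sapply(seq_len(N), function(n) {
    rows <- ((n - 1) * L + 1):(n * L)
    which.max(colSums(probs[rows, ]))
  })
  expect_equal(got, as.integer(want))

  # permuting rows within a subject leaves the labels unchanged
  perm <- as.numeric(sapply(seq_len(N), function(n) ((n - 1) * L) + sample(L)))
  expect_equal(merge_subject_clusters(probs[perm, ], ids[perm]), got)
  expect_error(merge_subject_clusters(probs[0, , drop = FALSE], character(0)))
})

test_that("PCA projection: diagonal score covariance, full-retention
           reconstruction, eigen oracle", {
  set.seed(5)
  X <- matrix(rnorm(200 * 6), 200, 6) %*% matrix(rnorm(36), 6, 6)
  pc <- pca_project(X, variance_kept = 1)
  cv <- cov(pc$scores)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-8)
  # full retention reconstructs exactly
  rec <- pc$scores %*% t(pc$rotation) + matrix(pc$center, 200, 6, byrow = TRUE)
  expect_equal(rec, X, tolerance = 1e-8)
  # eigenvalues match a direct eigendecomposition of the sample covariance
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(pc$sdev^2, ev[seq_along(pc$sdev)], tolerance = 1e-8)
  # rank-deficient input drops null directions
  Xr <- cbind(X[, 1:3], X[, 1:3])
  pcr <- pca_project(Xr)
  expect_lte(ncol(pcr$scores), 3L)
  expect_equal(pca_apply(pcr, Xr), pcr$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("VAE KL vanishes for a matched standard normal posterior", {
  ns <- asNamespace("vada")
  d <- tiny_real_data(N = 3L, L = 2L, P = 3L)
  nets <- tiny_nets(d, D = 2L, init = "zero")  # mu = 0, log-variance = 0
  meta <- ns$net_meta(nets)
  tp <- ns$ad_tape()
  wn <- grep("^(xe_|xd_)", names(nets), value = TRUE)
  wnodes <- setNames(lapply(wn, function(n) ns$ad_param(tp, nets[[n]])), wn)
  eps <- matrix(0, nrow(d$X), 2)
  ob <- ns$elbo_x_tape(tp, wnodes, NULL, d$X, eps, meta, "stdnormal")
  # posterior N(0, 1) matches the prior exactly, so the objective is the
  # pure reconstruction term under the zero-mean unit-variance decoder
  want <- sum(dnorm(d$X, 0, 1, log = TRUE)) / nrow(d$X)
  expect_equal(ob$elbo$value[1], want, tolerance = 1e-10)
})

test_that("VaDE with one component equals a learned-prior VAE term by term", {
  ns <- asNamespace("vada")
  set.seed(6)
  d <- tiny_real_data(N = 4L, L = 2L, P = 3L, seed = 6)
  nets <- tiny_nets(d, D = 2L)
  meta <- ns$net_meta(nets)
  wn <- grep("^(xe_|xd_)", names(nets), value = TRUE)
  mu1 <- matrix(rnorm(2), 1, 2); ls1 <- matrix(rnorm(2, 0, 0.3), 1, 2)
  eps <- matrix(rnorm(nrow(d$X) * 2), nrow(d$X), 2)
  tp <- ns$ad_tape()
  wnodes <- setNames(lapply(wn, function(n) ns$ad_param(tp, nets[[n]])), wn)
  un <- list(pi_logit = ns$ad_param(tp, matrix(0, 1, 1)),
             mu = ns$ad_param(tp, mu1), log_sigma2 = ns$ad_param(tp, ls1))
  ob <- ns$elbo_x_tape(tp, wnodes, un, d$X, eps, meta, "mixture")
  # closed-form learned-prior VAE reference
  enc <- apply_x_encoder(nets, d$X)
  z <- enc$mu + sqrt(enc$sigma2) * eps
  dec <- apply_x_decoder(nets, z)
  recon <- sum(dnorm(d$X, dec$mu, sqrt(dec$sigma2), log = TRUE))
  s2 <- matrix(exp(ls1), nrow(z), 2, byrow = TRUE)
  mu_m <- matrix(mu1, nrow(z), 2, byrow = TRUE)
  kl <- 0.5 * sum(log(s2 / enc$sigma2) + (enc$sigma2 + (enc$mu - mu_m)^2) / s2 - 1)
  expect_equal(ob$elbo$value[1], (recon - kl) / nrow(z), tolerance = 1e-8)
})

test_that("VaDE recovers well-separated observation-level clusters", {
  # latent Gaussian mixture pushed through a random linear decoder, so the
  # cluster directions load on every feature
  set.seed(7)
  n <- 600L; P <- 10L
  cl <- sample(3L, n, TRUE)
  mu <- matrix(c(5, 0, -2.5, 4.3, -2.5, -4.3), 3, 2, byrow = TRUE)
  Z <- mu[cl, ] + matrix(rnorm(n * 2), n, 2)
  X <- Z %*% matrix(rnorm(2 * P), 2, P) + 0.3 * matrix(rnorm(n * P), n, P)
  fk <- replicate(P, list(kind = "continuous"), simplify = FALSE)
  d <- vada_data(paste0("s", 1:n), X, matrix(rnorm(n), n, 1), fk)
  sd_ <- standardize(d)
  fit <- fit_vade(sd_$data, D = 2L, K = 3L, epochs = 200L, batch_obs = 128L,
                  seed = 2L, warmstart_epoch = 100L)
  probs <- vada:::vade_obs_probs(fit, sd_$data$X)
  expect_gte(ari(cl, max.col(probs)), 0.9)
})

test_that("baseline pipeline equals its manual stage-by-stage composition", {
  set.seed(8)
  gen <- generate_scenario(scenario_config("00", n_subjects = 150L, P = 8L,
                                           D_true = 4L, K_true = 2L, seed = 9L))
  sp <- split_subjects(gen$data, 0.8, seed = 9L)
  fit <- fit_baseline(sp$train, method = "gmm-mm", K = 2L,
                      working = "exchangeable", seed = 9L)
  pred <- predict(fit, sp$test)

  # manual composition with the same stages
  std <- standardize(sp$train)
  tst <- standardize(sp$test, std$stats)$data
  gmm <- vada:::fit_gmm(std$data$X, 2L)
  labs <- merge_subject_clusters(vada:::gmm_probs(gmm, std$data$X), rep(std$data$subject_ids, each = 4L))
  pca <- pca_project(std$data$X)
  gee <- fit_cluster_gee(pca$scores, std$data$y, labs, 2L, "exchangeable")
  probs_t <- vada:::gmm_probs(gmm, tst$X)
  labs_t <- merge_subject_clusters(probs_t, rep(tst$subject_ids, each = 4L))
  scores_t <- vada:::pca_apply(pca, tst$X)
  yhat <- matrix(NA_real_, tst$N, tst$L)
  for (k in 1:2) {
    subj <- which(labs_t == k)
    rows <- as.numeric(t(outer(subj - 1L, 1:4, function(a, b) a * 4L + b)))
    yhat[subj, ] <- matrix(predict(gee[[k]], cbind(1, scores_t[rows, ])),
                           length(subj), 4L, byrow = TRUE)
  }
  expect_equal(pred$y_hat, yhat, tolerance = 1e-10)
  expect_equal(pred$labels, labs_t)

  # well-separated linear scenario: near-noise-level test error
  y_std <- standardize(sp$test, std$stats)$data$y
  expect_lt(mse(y_std, pred$y_hat), 3 * gen$gen$noise_var_std)
})

test_that("a single-cluster pipeline reduces to one pooled GEE", {
  gen <- generate_scenario(scenario_config("00", n_subjects = 80L, P = 6L,
                                           D_true = 3L, K_true = 1L, seed = 10L))
  sp <- split_subjects(gen$data, 0.8, seed = 10L)
  fit <- fit_baseline(sp$train, method = "gmm-mm", K = 1L, working = "independence",
                      seed = 10L)
  pred <- predict(fit, sp$test)
  std <- standardize(sp$train)
  tst <- standardize(sp$test, std$stats)$data
  pca <- pca_project(std$data$X)
  g <- gee_fit(as.numeric(t(std$data$y)), cbind(1, pca$scores),
               rep(seq_len(std$data$N), each = 4L), "independence")
  want <- matrix(predict(g, cbind(1, vada:::pca_apply(pca, tst$X))),
                 tst$N, 4L, byrow = TRUE)
  expect_equal(pred$y_hat, want, tolerance = 1e-10)
})
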