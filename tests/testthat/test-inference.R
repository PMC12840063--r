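# a small fitted-like model assembled by hand (no training needed)
toy_fit <- function(D = 2L, K = 2L, seed = 3L, data = NULL, init = "glorot") {
  if (is.null(data)) data <- tiny_real_data(N = 6L, L = 2L, P = 3L, seed = seed)
  nets <- tiny_nets(data, D = D, seed = seed, init = init)
  params <- random_params(K = K, D = D, seed = seed)
  structure(list(nets = nets, params = params, stats = NULL,
                 history = tibble::tibble(),
                 config = list(D = D, K = K)), class = "vada_fit")
}

test_that("feature encoding returns posterior means, batched = rowwise", {
  d <- tiny_real_data(N = 5L, L = 2L, P = 3L)
  fit <- toy_fit(data = d)
  Z <- encode_features(fit, d)
  ref <- apply_x_encoder(fit$nets, d$X)$mu
  expect_identical(Z, ref)
  for (i in sample(nrow(d$X), 3)) {
    expect_equal(Z[i, ], apply_x_encoder(fit$nets, d$X[i, , drop = FALSE])$mu[1, ],
                 tolerance = 1e-12)
  }
  # zeroed encoder: representation equals the bias
  fit0 <- toy_fit(data = d, init = "zero")
  fit0$nets$xe_b_m[] <- c(1.5, -2)
  Z0 <- encode_features(fit0, d)
  expect_true(all(Z0[, 1] == 1.5 & Z0[, 2] == -2))
})

test_that("clustering rules: single cluster, ties, and the M=1 density oracle", {
  d <- tiny_real_data(N = 6L, L = 2L, P = 3L)
  fit1 <- toy_fit(K = 1L, data = d)
  fit1$params <- vada_params(1, matrix(0, 1, 2), matrix(1, 1, 2), 0,
                             matrix(0, 1, 2), 1)
  expect_true(all(cluster_yx(fit1, d, M = 5L)$labels == 1L))
  expect_true(all(cluster_x(fit1, d, M = 5L)$labels == 1L))

  # exact tie breaks to the lowest index
  expect_equal(vada:::argmax_rows(matrix(c(0.5, 0.5, 0.2, 0.8), 2, 2,
                                         byrow = TRUE)), c(1L, 2L))

  # identical components: x-rule probabilities are exactly (0.5, 0.5)
  fit2 <- toy_fit(K = 2L, data = d)
  fit2$params <- vada_params(c(0.5, 0.5), matrix(0.3, 2, 2), matrix(1.2, 2, 2),
                             c(0.1, 0.1), matrix(0.4, 2, 2), c(1, 1))
  px <- cluster_x(fit2, d, M = 3L, seed = 2L)$probs
  expect_equal(px, matrix(0.5, d$N, 2), tolerance = 1e-12)

  # M = 1: matches an independent per-subject loop over the z-branch densities
  fit3 <- toy_fit(K = 3L, data = d, seed = 8L)
  got <- cluster_x(fit3, d, M = 1L, seed = 6L)$probs
  ez <- apply_x_encoder(fit3$nets, d$X)
  set.seed(6L)
  Z <- ez$mu + sqrt(ez$sigma2) * matrix(rnorm(length(ez$mu)), nrow(ez$mu))
  p <- fit3$params
  for (n in seq_len(d$N)) {
    rows <- ((n - 1) * d$L + 1):(n * d$L)
    w <- sapply(seq_len(p$K), function(k) {
      p$pi[k] * prod(dnorm(Z[rows, ], matrix(p$mu[k, ], d$L, 2, byrow = TRUE),
                           matrix(sqrt(p$sigma2[k, ]), d$L, 2, byrow = TRUE)))
    })
    expect_equal(got[n, ], w / sum(w), tolerance = 1e-10)
  }
})

test_that("x-rule probabilities stabilize as M grows", {
  d <- tiny_real_data(N = 4L, L = 2L, P = 3L)
  fit <- toy_fit(K = 2L, data = d, seed = 10L)
  ref <- cluster_x(fit, d, M = 4000L, seed = 1L)$probs
  devs <- sapply(c(1, 10, 100, 1000), function(M) {
    max(abs(cluster_x(fit, d, M = M, seed = 2L)$probs - ref))
  })
  expect_lt(devs[4], devs[1] + 1e-12)
  expect_lt(devs[4], 0.05)
})

test_that("prediction pipeline equals a hand-rolled encode-linear-decode-mix", {
  d <- tiny_real_data(N = 5L, L = 2L, P = 3L, seed = 12L)
  fit <- toy_fit(K = 2L, data = d, seed = 12L)
  pred <- predict_outcomes(fit, d, M = 50L, seed = 4L)
  zhat <- apply_x_encoder(fit$nets, d$X)$mu
  q <- vada:::cluster_x_probs(zhat, apply_x_encoder(fit$nets, d$X)$sigma2,
                              d$N, d$L, fit$params, 50L, 4L)
  want <- matrix(0, d$N, d$L)
  for (k in 1:2) {
    u_k <- matrix(fit$params$beta0[k] + zhat %*% fit$params$beta[k, ],
                  d$N, d$L, byrow = TRUE)
    want <- want + q[, k] * apply_y_decoder(fit$nets, u_k)$mu
  }
  expect_equal(pred$y_hat, want, tolerance = 1e-8)
  expect_equal(pred$cluster_probs_x, q, tolerance = 1e-12)

  # identical cluster parameters: prediction reduces to the K = 1 case
  fit_same <- fit
  fit_same$params <- vada_params(c(0.3, 0.7), matrix(0.2, 2, 2),
                                 matrix(1, 2, 2), c(0.5, 0.5),
                                 matrix(0.3, 2, 2), c(1, 1))
  p2 <- predict_outcomes(fit_same, d, M = 20L, seed = 5L)
  u1 <- matrix(0.5 + zhat %*% c(0.3, 0.3), d$N, d$L, byrow = TRUE)
  expect_equal(p2$y_hat, apply_y_decoder(fit$nets, u1)$mu, tolerance = 1e-10)
})

test_that("prediction is deterministic given (weights, M, seed)", {
  d <- tiny_real_data(N = 4L, L = 2L, P = 3L)
  fit <- toy_fit(data = d)
  a <- predict_outcomes(fit, d, M = 10L, seed = 3L)
  b <- predict_outcomes(fit, d, M = 10L, seed = 3L)
  expect_identical(a$y_hat, b$y_hat)
})

test_that("label permutation of fitted components permutes outputs consistently", {
  d <- tiny_real_data(N = 8L, L = 2L, P = 3L, seed = 20L)
  fit <- toy_fit(K = 3L, data = d, seed = 20L)
  perm <- c(2L, 3L, 1L)
  fitp <- fit
  p <- fit$params
  fitp$params <- vada_params(p$pi[perm], p$mu[perm, ], p$sigma2[perm, ],
                             p$beta0[perm], p$beta[perm, ], p$sigma2_u[perm])
  a <- predict_outcomes(fit, d, M = 200L, seed = 2L)
  b <- predict_outcomes(fitp, d, M = 200L, seed = 2L)
  expect_equal(a$y_hat, b$y_hat, tolerance = 1e-6)
  expect_equal(ari(a$labels_x, b$labels_x), 1)
})

test_that("out-of-sample generation delegates to the generative process", {
  d <- tiny_real_data(N = 4L, L = 2L, P = 3L)
  fit <- toy_fit(data = d)
  g0 <- generate_subjects(fit, 0L)
  expect_equal(g0$N, 0L)
  g <- generate_subjects(fit, 2500L, seed = 3L)
  ref <- sample_generative(fit$params, fit$nets, 2500L, seed = 3L)
  expect_identical(g$X, ref$X)
  # covariate marginal means match the model-implied means within 4 SE
  dx <- apply_x_decoder(fit$nets, g$truth$Z_true)
  for (p_ in 1:3) {
    se <- sd(g$X[, p_]) / sqrt(nrow(g$X))
    expect_lt(abs(mean(g$X[, p_]) - mean(dx$mu[, p_])), 4 * se + 4 * sd(dx$mu[, p_]) / sqrt(nrow(g$X)))
  }
})
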