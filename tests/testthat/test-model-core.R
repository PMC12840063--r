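test_that("parameter and data containers enforce their invariants", {
  expect_error(vada_params(c(0.6, 0.6), matrix(0, 2, 1), matrix(1, 2, 1),
                           c(0, 0), matrix(0, 2, 1), c(1, 1)), "simplex")
  expect_error(vada_params(c(0.5, 0.5), matrix(0, 2, 1), matrix(c(1, -1), 2, 1),
                           c(0, 0), matrix(0, 2, 1), c(1, 1)), "positive")
  d <- tiny_mixed_data()
  expect_equal(d$N, 4L)
  Xbad <- d$X; Xbad[2, 2] <- 9  # outside declared category range
  expect_error(vada_data(d$subject_ids, Xbad, d$y, d$feature_kinds), "codes outside")
  ybad <- d$y; ybad[1, 1] <- NA
  expect_error(vada_data(d$subject_ids, d$X, ybad, d$feature_kinds), "missing")
})

test_that("responsibilities: single component, symmetry, and brute-force oracle", {
  p1 <- vada_params(1, matrix(0, 1, 2), matrix(1, 1, 2), 0, matrix(0, 1, 2), 1)
  expect_identical(responsibilities(c(0.3, -1), matrix(rnorm(4), 2, 2), p1), 1)

  # identical components with equal weights
  p2 <- vada_params(c(0.5, 0.5), matrix(1, 2, 2), matrix(2, 2, 2),
                    c(0.5, 0.5), matrix(1, 2, 2), c(1, 1))
  r <- responsibilities(c(0.3, -1), matrix(rnorm(4), 2, 2), p2)
  expect_equal(r, c(0.5, 0.5), tolerance = 1e-12)

  set.seed(77)
  for (i in 1:20) {
    p <- random_params(K = 3L, D = 2L, seed = i)
    u <- rnorm(2); Z <- matrix(rnorm(4), 2, 2)
    r <- responsibilities(u, Z, p)
    expect_equal(sum(r), 1, tolerance = 1e-12)
    expect_equal(r, oracle_responsibilities(u, Z, p), tolerance = 1e-10)
  }
})

test_that("responsibilities are invariant to common rescaling of densities", {
  # scaling all sigma2_u by the same factor changes every component density
  # by a common factor only when u happens to sit at all means; instead test
  # the normalization property directly: multiplying pi by a constant
  # (renormalized internally through the log-space path) leaves output fixed
  p <- random_params(K = 3L, D = 2L, seed = 9)
  u <- rnorm(2); Z <- matrix(rnorm(4), 2, 2)
  r1 <- responsibilities(u, Z, p)
  # shift all log-weights by a constant: equivalent brute-force check
  w <- oracle_responsibilities(u, Z, p)
  expect_equal(r1, w / sum(w), tolerance = 1e-12)
})

test_that("complete-data log-likelihood: mode arithmetic, oracle, monotonicity", {
  # zero data through zero-initialized nets: every Gaussian factor sits at
  # its mode with unit variance
  N <- 1L; L <- 2L; P <- 3L; D <- 2L
  d <- tiny_real_data(N = 2L, L = L, P = P)
  nets <- tiny_nets(d, D = D, init = "zero")
  p1 <- vada_params(1, matrix(0, 1, D), matrix(1, 1, D), 0, matrix(0, 1, D), 1)
  val <- complete_data_loglik(rep(0, L), rep(0, L), matrix(0, L, P),
                              matrix(0, L, D), 1L, p1, nets)
  expect_equal(val, -0.5 * (L + L * P + L + D * L) * log(2 * pi), tolerance = 1e-12)

  # per-factor oracle on random instances (mixed-type data)
  dm <- tiny_mixed_data()
  netm <- tiny_nets(dm, D = D)
  meta <- vada:::net_meta(netm)
  set.seed(101)
  for (i in 1:100) {
    p <- random_params(K = 2L, D = D, seed = 1000 + i)
    y <- rnorm(2); u <- rnorm(2); Z <- matrix(rnorm(4), 2, 2)
    X <- cbind(rnorm(2), sample(3, 2, TRUE), rnorm(2))
    cl <- sample(2, 1)
    got <- complete_data_loglik(y, u, X, Z, cl, p, netm)
    dy <- apply_y_decoder(netm, matrix(u, 1))
    dx <- apply_x_decoder(netm, Z)
    want <- sum(dnorm(y, dy$mu, sqrt(dy$sigma2), log = TRUE)) +
      sum(dnorm(X[, c(1, 3)], dx$mu, sqrt(dx$sigma2), log = TRUE)) +
      sum(log(dx$prob[[1]][cbind(1:2, X[, 2])])) +
      sum(dnorm(u, p$beta0[cl] + as.numeric(Z %*% p$beta[cl, ]),
                sqrt(p$sigma2_u[cl]), log = TRUE)) +
      sum(dnorm(Z, matrix(p$mu[cl, ], 2, 2, byrow = TRUE),
                matrix(sqrt(p$sigma2[cl, ]), 2, 2, byrow = TRUE), log = TRUE)) +
      log(p$pi[cl])
    expect_equal(got, want, tolerance = 1e-10)
  }

  # moving y away from the decoder mean strictly decreases the value
  p <- random_params(K = 2L, D = D, seed = 3)
  u <- rnorm(2); Z <- matrix(rnorm(4), 2, 2); X <- matrix(rnorm(6), 2, 3)
  dy <- apply_y_decoder(tiny_nets(d, D = D), matrix(u, 1))
  base_y <- as.numeric(dy$mu)
  nets2 <- tiny_nets(d, D = D)
  vals <- sapply(c(0, 0.5, 1, 2), function(delta) {
    yy <- base_y; yy[1] <- yy[1] + delta
    complete_data_loglik(yy, u, X, Z, 1L, p, nets2)
  })
  expect_true(all(diff(vals) < 0))
})

test_that("generative sampling is seed-reproducible and matches prior moments", {
  d <- tiny_real_data(P = 3L)
  nets <- tiny_nets(d, D = 1L)
  p <- vada_params(1, matrix(0.7, 1, 1), matrix(2.3, 1, 1), 0, matrix(1, 1, 1), 1)
  s1 <- sample_generative(p, nets, 40L, seed = 11L)
  s2 <- sample_generative(p, nets, 40L, seed = 11L)
  expect_identical(s1$X, s2$X)
  expect_identical(s1$y, s2$y)
  s3 <- sample_generative(p, nets, 40L, seed = 12L)
  expect_false(identical(s1$X, s3$X))

  # K=1, D=1: latent sample moments match (mu, sigma2) within 4 SE
  big <- sample_generative(p, nets, 2500L, seed = 5L)
  z <- big$truth$Z_true
  n <- length(z)
  expect_lt(abs(mean(z) - 0.7), 4 * sqrt(2.3 / n))
  se_var <- sqrt(2 * 2.3^2 / (n - 1))
  expect_lt(abs(var(as.numeric(z)) - 2.3), 4 * se_var)
})

test_that("sampled class frequencies follow the mixture weights", {
  d <- tiny_real_data(P = 2L)
  nets <- tiny_nets(d, D = 2L)
  p <- random_params(K = 3L, D = 2L, seed = 4)
  s <- sample_generative(p, nets, 20000L, seed = 8L)
  tab <- tabulate(s$truth$c_true, 3L)
  expect_gt(chisq.test(tab, p = p$pi)$p.value, 0.001)
})

test_that("dimension mismatch between params and nets is a configuration error", {
  d <- tiny_real_data()
  nets <- tiny_nets(d, D = 2L)
  p <- random_params(K = 2L, D = 3L)
  expect_error(sample_generative(p, nets, 5L), "mismatch")
})
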