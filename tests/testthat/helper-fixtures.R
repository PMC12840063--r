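# Small fixtures built in code. All dimensions are deliberately tiny; the
# full-scale benchmark conditions are exercised in the acceptance tests.

tiny_mixed_data <- function(N = 4L, L = 2L, seed = 42L) {
  set.seed(seed)
  fk <- list(list(kind = "continuous"),
             list(kind = "categorical", levels = c("a", "b", "c")),
             list(kind = "continuous"))
  X <- cbind(rnorm(N * L), sample(3L, N * L, TRUE), rnorm(N * L))
  y <- matrix(rnorm(N * L), N, L)
  vada_data(paste0("s", seq_len(N)), X, y, fk, "real")
}

tiny_real_data <- function(N = 4L, L = 2L, P = 3L, seed = 42L) {
  set.seed(seed)
  fk <- replicate(P, list(kind = "continuous"), simplify = FALSE)
  vada_data(paste0("s", seq_len(N)),
            matrix(rnorm(N * L * P), N * L, P),
            matrix(rnorm(N * L), N, L), fk, "real")
}

tiny_nets <- function(data, D = 2L, hidden_x = 5L, hidden_y = 4L,
                      seed = 7L, init = "glorot") {
  build_networks(vada_arch(hidden_x = hidden_x, hidden_y = hidden_y,
                           seed = seed, init = init),
                 vada:::data_spec(data, D))
}

random_params <- function(K = 2L, D = 2L, seed = 5L) {
  set.seed(seed)
  pr <- runif(K) + 0.2
  vada_params(pi = pr / sum(pr),
              mu = matrix(rnorm(K * D), K, D),
              sigma2 = matrix(exp(rnorm(K * D, 0, 0.3)), K, D),
              beta0 = rnorm(K),
              beta = matrix(rnorm(K * D), K, D),
              sigma2_u = exp(rnorm(K, 0, 0.3)))
}

random_uncon <- function(K = 2L, D = 2L, seed = 5L) {
  set.seed(seed)
  list(pi_logit = matrix(rnorm(K), 1L),
       mu = matrix(rnorm(K * D), K, D),
       log_sigma2 = matrix(rnorm(K * D, 0, 0.3), K, D),
       beta0 = matrix(rnorm(K), 1L),
       beta = matrix(rnorm(K * D), K, D),
       log_sigma2_u = matrix(rnorm(K, 0, 0.3), 1L, K))
}

# straight-line responsibilities oracle: direct product of densities
oracle_responsibilities <- function(u, Z, params) {
  K <- params$K
  w <- numeric(K)
  for (k in seq_len(K)) {
    pu <- prod(dnorm(u, params$beta0[k] + as.numeric(Z %*% params$beta[k, ]),
                     sqrt(params$sigma2_u[k])))
    pz <- 1
    for (l in seq_len(nrow(Z))) {
      pz <- pz * prod(dnorm(Z[l, ], params$mu[k, ], sqrt(params$sigma2[k, ])))
    }
    w[k] <- params$pi[k] * pu * pz
  }
  w / sum(w)
}
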