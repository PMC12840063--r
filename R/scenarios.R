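#' Synthetic benchmark scenario configuration
#'
#' Four generating regimes, coded by whether the outcome side uses the
#' coupling Y-decoder (first digit) and whether the feature side uses a
#' deep decoder (second digit):
#' \describe{
#'   \item{"11"}{Well-specified: latent cluster Gaussians, deep X-decoder
#'     for features, cluster-linear pure outcomes, deep Y-decoder coupling
#'     the measurements of a subject.}
#'   \item{"01"}{Features as in 11; outcomes are an independent per-cluster
#'     nonlinear map of each measurement's latent (no cross-measurement
#'     coupling).}
#'   \item{"10"}{Features drawn directly from a diagonal-covariance
#'     Gaussian mixture in feature space; pure outcomes linear in the
#'     informative feature coordinates; deep Y-decoder coupling.}
#'   \item{"00"}{Features as in 10; outcomes a per-cluster linear
#'     regression on the informative coordinates with independent noise.}
#' }
#' Defaults reproduce the benchmark conditions: 2500 subjects, 4
#' measurements, 100 features, 3 equally likely clusters with
#' 10-dimensional latent structure, cluster centers at distance 6 from the
#' origin along random orthogonal directions, unit component variances, and
#' noise of sd 0.2 added after the deterministic part of each generated
#' block is standardized.
#'
#' @param code Scenario code: "11", "01", "10" or "00".
#' @param n_subjects,L,P,K_true,D_true Dimensions of the generated data.
#' @param separation Distance of cluster centers from the origin.
#' @param noise_x,noise_u,noise_y Noise standard deviations (applied on the
#'   standardized scale of the corresponding deterministic part).
#' @param seed Integer seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(code, n_subjects = 2500L, L = 4L, P = 100L,
                            K_true = 3L, D_true = 10L, separation = 6,
                            noise_x = 0.2, noise_u = 0.2, noise_y = 0.2,
                            seed = 1L) {
  code <- as.character(code)
  if (!code %in% c("11", "01", "10", "00")) stop("invalid scenario code: ", code)
  stopifnot(n_subjects >= 1L, L >= 1L, P >= D_true, K_true >= 1L,
            D_true >= K_true)
  structure(list(code = code, n_subjects = as.integer(n_subjects),
                 L = as.integer(L), P = as.integer(P),
                 K_true = as.integer(K_true), D_true = as.integer(D_true),
                 separation = separation, noise_x = noise_x,
                 noise_u = noise_u, noise_y = noise_y,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

std_cols <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  sweep(sweep(m, 2L, mu), 2L, sd, "/")
}

# single affine map for a whole block: preserves structural properties such
# as a shared per-cluster linear model across measurements
std_all <- function(m) {
  s <- stats::sd(as.numeric(m))
  if (!is.finite(s) || s < 1e-8) s <- 1
  (m - mean(m)) / s
}

# frozen random one-hidden-layer tanh net (generator side)
rand_net <- function(n_in, n_hidden, n_out) {
  list(W1 = glorot_mat(n_in, n_hidden), W2 = glorot_mat(n_hidden, n_out))
}
rand_net_fwd <- function(net, x) tanh(x %*% net$W1) %*% net$W2

#' Generate a synthetic benchmark dataset
#'
#' Draws one dataset under the configured scenario; see
#' [scenario_config()] for the regimes. The generating networks are frozen
#' random draws with the default architecture (they are never the fitted
#' model's networks). Deterministic per seed.
#'
#' @param config A [scenario_config()] object.
#' @return A list with `data` (a [vada_data()] with truth filled) and
#'   `gen`, the generating quantities: cluster labels, latent means, the
#'   informative coordinate set (scenarios 10/00), and
#'   `noise_var_std`, the irreducible outcome noise variance on the
#'   standardized outcome scale.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  N <- config$n_subjects; L <- config$L; P <- config$P
  K <- config$K_true; D <- config$D_true
  code <- config$code
  # first digit: coupling Y-decoder active; second digit: deep X-decoder
  # active ("01" uses only the X-decoder, "10" only the Y-decoder)
  deep_y <- substr(code, 1L, 1L) == "1"
  deep_x <- substr(code, 2L, 2L) == "1"

  c_true <- sample.int(K, N, replace = TRUE)
  cl_obs <- rep(c_true, each = L)
  Q <- qr.Q(qr(matrix(stats::rnorm(D * D), D, D)))
  mu_lat <- config$separation * t(Q[, seq_len(K), drop = FALSE])  # K x D
  beta0 <- stats::rnorm(K)
  beta <- matrix(stats::rnorm(K * D), K, D)

  if (deep_x) {
    # latent cluster Gaussians -> deep feature decoder
    Z <- mu_lat[cl_obs, , drop = FALSE] + matrix(stats::rnorm(N * L * D), N * L, D)
    fx <- rand_net(D, 64L, P)
    X <- std_cols(rand_net_fwd(fx, Z)) +
      config$noise_x * matrix(stats::rnorm(N * L * P), N * L, P)
    inf_idx <- NULL
  } else {
    # diagonal-covariance Gaussian mixture directly in feature space;
    # cluster structure lives in a random informative coordinate block
    inf_idx <- sort(sample.int(P, D))
    mu_x <- matrix(0, K, P)
    mu_x[, inf_idx] <- mu_lat
    X <- mu_x[cl_obs, , drop = FALSE] + matrix(stats::rnorm(N * L * P), N * L, P)
    Z <- X[, inf_idx, drop = FALSE]
  }

  lin_part <- beta0[cl_obs] + rowSums(Z * beta[cl_obs, , drop = FALSE])
  y_rep <- NULL  # an independent outcome draw sharing Z, for the noise floor
  if (deep_y) {
    lin_std <- as.numeric(std_cols(matrix(lin_part, ncol = 1L)))
    u_obs <- lin_std + config$noise_u * stats::rnorm(N * L)
    u <- matrix(u_obs, N, L, byrow = TRUE)
    fy <- rand_net(L, 16L, L)
    y_det <- std_all(rand_net_fwd(fy, u))
    # second draw with fresh pure-outcome noise: the irreducible prediction
    # variance given the latents includes noise propagated through the
    # coupling decoder, E[var(y|Z)] = E[(y - y')^2]/2
    u2 <- matrix(lin_std + config$noise_u * stats::rnorm(N * L), N, L, byrow = TRUE)
    y_rep <- std_all(rand_net_fwd(fy, u2)) +
      config$noise_y * matrix(stats::rnorm(N * L), N, L)
  } else if (code == "01") {
    # independent per-measurement nonlinear map of the cluster-centered latent
    mc <- lapply(seq_len(K), function(k) rand_net(D, 16L, 1L))
    zc <- Z - mu_lat[cl_obs, , drop = FALSE]
    yv <- numeric(N * L)
    for (k in seq_len(K)) {
      rows <- cl_obs == k
      yv[rows] <- rand_net_fwd(mc[[k]], zc[rows, , drop = FALSE])
    }
    u <- matrix(yv, N, L, byrow = TRUE)
    y_det <- std_all(matrix(yv, N, L, byrow = TRUE))
  } else {  # "00": plain per-cluster linear regression on informative coords
    u <- matrix(lin_part, N, L, byrow = TRUE)
    y_det <- std_all(matrix(lin_part, N, L, byrow = TRUE))
  }
  y <- y_det + config$noise_y * matrix(stats::rnorm(N * L), N, L)

  fk <- replicate(P, list(kind = "continuous"), simplify = FALSE)
  data <- vada_data(paste0("s", seq_len(N)), X, y, fk, "real",
                    truth = list(c_true = c_true, Z_true = Z, u_true = u))
  # Irreducible outcome variance on the standardized scale. Uncoupled
  # scenarios: y = unit-variance deterministic part + noise, so the floor is
  # noise^2 / (1 + noise^2) in closed form. Coupled scenarios: pure-outcome
  # noise also propagates through the Y-decoder; estimated from the paired
  # outcome draw sharing the latents.
  noise_var_std <- if (deep_y) {
    mean((y - y_rep)^2) / 2 / stats::var(as.numeric(y))
  } else {
    config$noise_y^2 / (1 + config$noise_y^2)
  }
  list(data = data,
       gen = list(c_true = c_true, mu_lat = mu_lat, beta0 = beta0, beta = beta,
                  inf_idx = inf_idx, noise_var_std = noise_var_std))
}
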