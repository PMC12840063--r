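#' Latent representations of feature data
#'
#' Encodes features to their posterior-mean latent representations
#' \eqn{\hat z = \tilde\mu_z} (no sampling).
#'
#' @param fit A `vada_fit` object (or a `vada_nets` bundle).
#' @param data A [vada_data()] object; when `fit` is a full fit its stored
#'   standardization statistics are applied first.
#' @return (N*L) x D matrix of latent means, subject-major rows.
#' @export
encode_features <- function(fit, data) {
  if (inherits(fit, "vada_fit")) {
    data <- apply_fit_stats(fit, data)
    nets <- fit$nets
  } else nets <- fit
  apply_x_encoder(nets, data$X)$mu
}

argmax_rows <- function(p) max.col(p, ties.method = "first")

#' Cluster subjects using outcomes and covariates
#'
#' The complete-data clustering rule: subjects are assigned to the argmax
#' of the Monte-Carlo cluster posterior q(c | y, X) (ties break to the
#' lowest index).
#'
#' @param fit A `vada_fit` object.
#' @param data A [vada_data()] object with outcomes present.
#' @param M Monte-Carlo samples (default 100).
#' @param seed Integer seed.
#' @return A list with integer `labels` (length N) and `probs` (N x K).
#' @export
cluster_yx <- function(fit, data, M = 100L, seed = 1L) {
  data <- apply_fit_stats(fit, data)
  state <- variational_state(fit$nets, data)
  samples <- reparameterized_samples(state, M, seed)
  probs <- mixture_posterior(samples, fit$params)
  list(labels = argmax_rows(probs), probs = probs)
}

#' Cluster subjects using covariates only
#'
#' The feature-only clustering rule: q(c = k | X) is approximated by
#' averaging the latent-branch responsibilities
#' p(Z | c = k) p(c = k) / sum over clusters, over `M` latent samples.
#'
#' @inheritParams cluster_yx
#' @return A list with integer `labels` and `probs` (N x K).
#' @export
cluster_x <- function(fit, data, M = 100L, seed = 1L) {
  data <- apply_fit_stats(fit, data)
  ez <- apply_x_encoder(fit$nets, data$X)
  probs <- cluster_x_probs(ez$mu, ez$sigma2, data$N, data$L, fit$params, M, seed)
  list(labels = argmax_rows(probs), probs = probs)
}

cluster_x_probs <- function(mu_z, sigma2_z, N, L, params, M, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  K <- params$K; D <- params$D
  grp <- rep(seq_len(N), each = L)
  acc <- matrix(0, N, K)
  for (m in seq_len(M)) {
    Z <- mu_z + sqrt(sigma2_z) * matrix(stats::rnorm(N * L * D), N * L, D)
    lw <- matrix(0, N, K)
    for (k in seq_len(K)) {
      ld <- rowSums(gauss_logdens(Z, matrix(params$mu[k, ], N * L, D, byrow = TRUE),
                                  matrix(params$sigma2[k, ], N * L, D, byrow = TRUE)))
      lw[, k] <- log(params$pi[k]) + as.numeric(rowsum(ld, grp, reorder = FALSE))
    }
    mx <- apply(lw, 1L, max)
    w <- exp(lw - mx)
    acc <- acc + w / rowSums(w)
  }
  acc / M
}

#' Predict outcomes from covariates
#'
#' Three-step pipeline: (i) encode features to posterior-mean latents
#' \eqn{\hat z}; (ii) insert them into the K cluster-specific marginal
#' models, \eqn{\hat u^k_l = \beta_{k0} + \hat z_l' \beta_k}; (iii) decode
#' each \eqn{\hat u^k} through the Y-decoder and mix the cluster-specific
#' predictions by q(c | X). For categorical outcomes the mixture-weighted
#' class probabilities are returned and the class is their argmax.
#'
#' @inheritParams cluster_yx
#' @return A `vada_pred` list with `y_hat` (N x L, standardized scale for
#'   real outcomes), `y_hat_orig` (original scale), `cluster_probs_x`,
#'   `cluster_probs_yx` (NULL when outcomes are absent from `data`),
#'   `labels_x`, `labels_yx`, and for categorical outcomes `class_probs`.
#' @export
predict_outcomes <- function(fit, data, M = 100L, seed = 1L) {
  sdata <- apply_fit_stats(fit, data)
  meta <- net_meta(fit$nets)
  N <- sdata$N; L <- sdata$L
  ez <- apply_x_encoder(fit$nets, sdata$X)
  probs_x <- cluster_x_probs(ez$mu, ez$sigma2, N, L, fit$params, M, seed)
  params <- fit$params
  if (!meta$y_cat) {
    y_hat <- matrix(0, N, L)
    for (k in seq_len(params$K)) {
      uk <- matrix(params$beta0[k] + as.numeric(ez$mu %*% params$beta[k, ]),
                   N, L, byrow = TRUE)
      yk <- apply_y_decoder(fit$nets, uk)$mu
      y_hat <- y_hat + probs_x[, k] * yk
    }
    class_probs <- NULL
  } else {
    G <- meta$G_y
    class_probs <- lapply(seq_len(L), function(l) matrix(0, N, G))
    for (k in seq_len(params$K)) {
      uk <- matrix(params$beta0[k] + as.numeric(ez$mu %*% params$beta[k, ]),
                   N, L, byrow = TRUE)
      pk <- apply_y_decoder(fit$nets, uk)$prob
      for (l in seq_len(L)) class_probs[[l]] <- class_probs[[l]] + probs_x[, k] * pk[[l]]
    }
    y_hat <- do.call(cbind, lapply(class_probs, argmax_rows))
  }
  yx <- tryCatch(cluster_yx(fit, data, M = M, seed = seed), error = function(e) NULL)
  structure(list(
    y_hat = y_hat,
    y_hat_orig = if (!meta$y_cat && !is.null(fit$stats)) unstandardize_y(y_hat, fit$stats) else y_hat,
    class_probs = class_probs,
    cluster_probs_x = probs_x,
    labels_x = argmax_rows(probs_x),
    cluster_probs_yx = if (!is.null(yx)) yx$probs else NULL,
    labels_yx = if (!is.null(yx)) yx$labels else NULL,
    subject_ids = data$subject_ids), class = "vada_pred")
}

#' @export
predict.vada_fit <- function(object, newdata, M = 100L, seed = 1L, ...) {
  predict_outcomes(object, newdata, M = M, seed = seed)
}

#' Generate new subjects from a fitted model
#'
#' Draws subjects from the fitted generative process (on the standardized
#' scale the model was trained on).
#'
#' @param fit A `vada_fit` object.
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @return A [vada_data()] object with truth fields filled.
#' @export
generate_subjects <- function(fit, n, seed = 1L) {
  sample_generative(fit$params, fit$nets, n, seed)
}
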