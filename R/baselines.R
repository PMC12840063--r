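# Baseline stack: VaDE and VAE auto-encoders over i.i.d. observations
# (sharing the X-encoder/decoder architecture), Gaussian-mixture
# clustering, subject-level probability merging, PCA projection, and the
# cluster-specific marginal-model pipelines.

# differentiable per-observation ELBO for the x-branch only.
# prior = "mixture" (VaDE) or "stdnormal" (VAE). True-KL convention
# (constants included), so a matched standard normal gives KL = 0.
elbo_x_tape <- function(tp, wts, un, Xb, eps, meta, prior) {
  n <- nrow(Xb); D <- meta$D
  act <- meta$arch$activation
  Xe <- expand_features(Xb, meta)
  enc <- ad_dense(tp, wts, "xe_", Xe, act, c("m", "v"))
  mu_z <- enc$m
  lv_z <- ad_clamp_min(tp, enc$v, LOGV_FLOOR)
  z <- ad_reparam(tp, mu_z, enc$v, eps)
  xd_heads <- c(if (length(meta$con_idx)) c("m", "v"),
                if (length(meta$cat_idx)) paste0("c", seq_along(meta$cat_idx)))
  dec <- ad_dense(tp, wts, "xd_", z, act, xd_heads)
  rx_sum <- NULL
  if (length(meta$con_idx)) {
    rx_sum <- ad_gauss_recon(tp, Xb[, meta$con_idx, drop = FALSE], dec$m, dec$v)
  }
  if (length(meta$cat_idx)) {
    for (j in seq_along(meta$cat_idx)) {
      logits <- dec[[paste0("c", j)]]
      lp <- ad_sub(tp, logits, ad_lse_rows(tp, logits))
      oh <- matrix(0, n, meta$cat_G[j])
      oh[cbind(seq_len(n), Xb[, meta$cat_idx[j]])] <- 1
      term <- ad_sum(tp, ad_mul(tp, lp, ad_const(tp, oh)))
      rx_sum <- if (is.null(rx_sum)) term else ad_add(tp, rx_sum, term)
    }
  }
  s2_z <- ad_exp(tp, lv_z)
  if (prior == "stdnormal") {
    kl_rows <- ad_scale(tp, ad_rowsum(tp, ad_addc(tp, ad_sub(tp,
                 ad_add(tp, ad_sqr(tp, mu_z), s2_z), lv_z), -1)), 0.5)
    gamma <- NULL
  } else {
    K <- nrow(un$mu$value)
    log_pi <- ad_sub(tp, un$pi_logit, ad_lse_rows(tp, un$pi_logit))
    lg_cols <- vector("list", K); A_cols <- vector("list", K)
    for (k in seq_len(K)) {
      mu_k <- ad_getrow(tp, un$mu, k)
      lv_k <- ad_getrow(tp, un$log_sigma2, k)
      dz <- ad_sub(tp, z, mu_k)
      ld <- ad_rowsum(tp, ad_scale(tp, ad_addc(tp, ad_add(tp,
             ad_mul(tp, ad_sqr(tp, dz), ad_exp(tp, ad_neg(tp, lv_k))), lv_k),
             LOG2PI), -0.5))
      lg_cols[[k]] <- ad_add(tp, ld, ad_getcol(tp, log_pi, k))
      qk <- ad_add(tp, ad_sqr(tp, ad_sub(tp, mu_z, mu_k)), s2_z)
      A_cols[[k]] <- ad_rowsum(tp, ad_addc(tp, ad_sub(tp, ad_add(tp,
                       ad_mul(tp, qk, ad_exp(tp, ad_neg(tp, lv_k))), lv_k),
                       lv_z), -1))
    }
    log_g <- ad_cbind(tp, lg_cols)
    gamma <- ad_softmax_rows(tp, log_g)
    A <- ad_cbind(tp, A_cols)
    lgam <- ad_log(tp, ad_clamp_min(tp, gamma, 1e-300))
    kl_rows <- ad_add(tp,
      ad_scale(tp, ad_rowsum(tp, ad_mul(tp, gamma, A)), 0.5),
      ad_rowsum(tp, ad_mul(tp, gamma, ad_sub(tp, lgam, log_pi))))
  }
  elbo_node <- ad_scale(tp, ad_sub(tp, rx_sum, ad_sum(tp, kl_rows)), 1 / n)
  list(elbo = elbo_node, gamma = gamma)
}

fit_x_autoencoder <- function(data, D, K, prior, epochs = 500L, batch_obs = 512L,
                              lr = 1e-3, seed = 1L, arch = vada_arch(),
                              verbose = 0L, warmstart_epoch = 30L) {
  arch$seed <- as.integer(seed)
  nets <- build_networks(arch, data_spec(data, D))
  meta <- net_meta(nets)
  wn <- grep("^(xe_|xd_)", names(nets), value = TRUE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  un <- if (prior == "mixture") {
    list(pi_logit = matrix(0, 1L, K), mu = matrix(stats::rnorm(K * D), K, D),
         log_sigma2 = matrix(0, K, D))
  } else NULL
  theta <- c(stats::setNames(lapply(wn, function(n) nets[[n]]), wn), un)
  opt <- adam_state(theta)
  n_obs <- nrow(data$X)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    # same mixture warm start as the main trainer (see vada()): re-localize
    # the Gaussian-mixture block on the burn-in latent means
    if (prior == "mixture" && warmstart_epoch > 0L && ep == warmstart_epoch + 1L &&
        K > 1L && epochs > warmstart_epoch) {
      wnets <- nets
      for (n in wn) wnets[[n]] <- theta[[n]]
      mu_z_all <- apply_x_encoder(wnets, data$X)$mu
      sub <- if (nrow(mu_z_all) > 2000L) sort(sample.int(nrow(mu_z_all), 2000L)) else seq_len(nrow(mu_z_all))
      gm <- tryCatch(fit_gmm(mu_z_all[sub, , drop = FALSE], K),
                     error = function(e) NULL)
      if (!is.null(gm) && !any(is.na(gm$parameters$mean))) {
        theta$mu <- t(gm$parameters$mean)
        sig <- gm$parameters$variance$sigma
        theta$log_sigma2 <- t(apply(sig, 3L, function(S) log(pmax(diag(S), VAR_FLOOR))))
        if (D == 1L) theta$log_sigma2 <- matrix(theta$log_sigma2, K, 1L)
        theta$pi_logit <- matrix(log(pmax(gm$parameters$pro, 1e-6)), 1L, K)
        for (nm in c("mu", "log_sigma2", "pi_logit")) {
          opt$m[[nm]][] <- 0; opt$v[[nm]][] <- 0
        }
      }
    }
    ord <- sample.int(n_obs)
    starts <- seq(1L, n_obs, by = batch_obs)
    tot <- 0
    for (s in starts) {
      rows <- ord[s:min(s + batch_obs - 1L, n_obs)]
      Xb <- data$X[rows, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(rows) * D), length(rows), D)
      tp <- ad_tape()
      wnodes <- stats::setNames(lapply(wn, function(n) ad_param(tp, theta[[n]])), wn)
      unodes <- if (prior == "mixture") {
        lapply(theta[c("pi_logit", "mu", "log_sigma2")], function(x) ad_param(tp, x))
      } else NULL
      ob <- elbo_x_tape(tp, wnodes, unodes, Xb, eps, meta, prior)
      loss <- ad_scale(tp, ob$elbo, -1)
      if (!is.finite(loss$value[1L])) stop("non-finite objective at epoch ", ep)
      ad_backward(tp, loss)
      grads <- c(lapply(wnodes, function(nd) nd$grad),
                 if (prior == "mixture") lapply(unodes, function(nd) nd$grad))
      upd <- adam_step(theta, grads, opt, lr = lr)
      theta <- upd$theta; opt <- upd$st
      tot <- tot + ob$elbo$value * length(rows) / n_obs
    }
    history[ep] <- tot
    if (verbose > 0L && ep %% verbose == 0L) {
      message(sprintf("epoch %4d  elbo %10.4f", ep, tot))
    }
  }
  for (n in wn) nets[[n]] <- theta[[n]]
  mix <- if (prior == "mixture") {
    pl <- as.numeric(theta$pi_logit)
    list(pi = exp(pl - max(pl)) / sum(exp(pl - max(pl))), mu = theta$mu,
         sigma2 = pmax(exp(theta$log_sigma2), VAR_FLOOR))
  } else NULL
  structure(list(nets = nets, mixture = mix, prior = prior, D = D, K = K,
                 history = history),
            class = if (prior == "mixture") "vade_fit" else "vae_fit")
}

#' Fit a VaDE baseline over i.i.d. observations
#'
#' A Gaussian-mixture-prior auto-encoder on the feature data, treating
#' every (subject, measurement) row independently. Shares the X-encoder
#' and X-decoder architecture of the main model.
#'
#' @param data A [vada_data()] object (already standardized if desired).
#' @param D Latent dimension.
#' @param K Number of mixture components.
#' @param epochs,batch_obs,lr,seed,arch,verbose Training controls
#'   (observation batches, default 512).
#' @param warmstart_epoch Mixture warm-start epoch, as in [vada()]; 0
#'   disables.
#' @return A `vade_fit` with `nets`, `mixture` (pi, mu, sigma2), history.
#' @export
fit_vade <- function(data, D, K, epochs = 500L, batch_obs = 512L, lr = 1e-3,
                     seed = 1L, arch = vada_arch(), verbose = 0L,
                     warmstart_epoch = 30L) {
  fit_x_autoencoder(data, D, K, "mixture", epochs, batch_obs, lr, seed, arch,
                    verbose, warmstart_epoch)
}

#' Fit a VAE baseline over i.i.d. observations
#'
#' Standard-normal-prior auto-encoder on the feature data; otherwise as
#' [fit_vade()].
#'
#' @inheritParams fit_vade
#' @return A `vae_fit` with `nets` and training history.
#' @export
fit_vae <- function(data, D, epochs = 500L, batch_obs = 512L, lr = 1e-3,
                    seed = 1L, arch = vada_arch(), verbose = 0L) {
  fit_x_autoencoder(data, D, 1L, "stdnormal", epochs, batch_obs, lr, seed, arch, verbose)
}

# Gaussian-mixture fit with diagonal component covariances (VVI), EM
# initialized from k-means: the default hierarchical initialization is
# quadratic in rows and unreliable in high dimension, and a conjugate
# prior guards against singular components.
fit_gmm <- function(X, K, nstart = 5L) {
  defaultPrior <- mclust::defaultPrior  # resolved by name inside meVVI
  X <- as_mat(X)
  km <- stats::kmeans(X, K, nstart = nstart, iter.max = 50L)
  z0 <- mclust::unmap(km$cluster, groups = seq_len(K))
  m <- mclust::meVVI(data = X, z = z0, prior = mclust::priorControl())
  if (is.null(m$parameters) || anyNA(m$parameters$pro)) {
    stop("Gaussian-mixture fit failed to converge")
  }
  structure(list(parameters = m$parameters, K = K, loglik = m$loglik),
            class = "vada_gmm")
}

# posterior component probabilities for (new) observations
gmm_probs <- function(g, X) {
  if (g$K == 1L) return(matrix(1, nrow(X), 1L))
  mclust::estepVVI(data = as_mat(X), parameters = g$parameters)$z
}

# per-observation cluster probabilities of a VaDE fit at the posterior mean
vade_obs_probs <- function(fit, X) {
  mu_z <- apply_x_encoder(fit$nets, X)$mu
  mix <- fit$mixture
  K <- length(mix$pi)
  lw <- matrix(0, nrow(mu_z), K)
  for (k in seq_len(K)) {
    lw[, k] <- log(mix$pi[k]) +
      rowSums(gauss_logdens(mu_z, matrix(mix$mu[k, ], nrow(mu_z), fit$D, byrow = TRUE),
                            matrix(mix$sigma2[k, ], nrow(mu_z), fit$D, byrow = TRUE)))
  }
  m <- apply(lw, 1L, max)
  w <- exp(lw - m)
  w / rowSums(w)
}

#' Merge per-observation cluster probabilities to subject labels
#'
#' Sums each subject's per-measurement cluster probabilities and assigns
#' the subject to the cluster with the highest total (ties to the lowest
#' index).
#'
#' @param probs (N*L) x K matrix of per-observation probabilities, rows
#'   grouped by subject.
#' @param subject_ids Length-(N*L) vector of subject identifiers.
#' @return Integer vector of per-subject labels (in order of first
#'   appearance of each subject).
#' @export
merge_subject_clusters <- function(probs, subject_ids) {
  probs <- as_mat(probs)
  stopifnot(nrow(probs) == length(subject_ids))
  if (!length(subject_ids)) stop("subject with zero rows")
  f <- factor(subject_ids, levels = unique(subject_ids))
  sums <- rowsum(probs, f, reorder = FALSE)
  argmax_rows(sums)
}

#' Center-and-project features by principal components
#'
#' @param features Numeric matrix (rows = observations).
#' @param variance_kept Cumulative variance fraction to retain (default
#'   0.9999); components with eigenvalue below 1e-8 are always dropped.
#' @return A `vada_pca` list with `scores`, `rotation`, `center`,
#'   `sdev`.
#' @export
pca_project <- function(features, variance_kept = 0.9999) {
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- which(cumsum(ev) / sum(ev) <= variance_kept + 1e-12)
  if (!length(keep)) keep <- 1L
  keep <- union(keep, seq_len(min(length(ev), max(keep) + 1L)))
  keep <- keep[ev[keep] > 1e-8]
  structure(list(scores = pc$x[, keep, drop = FALSE],
                 rotation = pc$rotation[, keep, drop = FALSE],
                 center = pc$center, sdev = pc$sdev[keep]),
            class = "vada_pca")
}

pca_apply <- function(pca, features) {
  sweep(features, 2L, pca$center) %*% pca$rotation
}

#' Fit a baseline clustering + marginal-model pipeline
#'
#' The three comparison pipelines: `"vade-mm"` (VaDE representation and
#' clustering), `"vae-gmm-mm"` (VAE representation, Gaussian-mixture
#' clustering of the embeddings), `"gmm-mm"` (Gaussian-mixture clustering
#' of the raw features). In all three, per-observation cluster
#' probabilities are merged to subject labels, the per-observation features
#' (embeddings, or raw features for `"gmm-mm"`) are projected to principal
#' components, and one GEE marginal model per cluster is fitted on the
#' scores under the requested working correlation.
#'
#' @param train A [vada_data()] training set.
#' @param method `"vade-mm"`, `"vae-gmm-mm"` or `"gmm-mm"`.
#' @param K Number of clusters.
#' @param D Latent dimension (ignored for `"gmm-mm"`).
#' @param working `"independence"` (MM0), `"ar1"` (MM1) or
#'   `"exchangeable"` (MM2).
#' @param link `"identity"` or `"logit"`.
#' @param epochs,lr,seed Training controls for the auto-encoder stage.
#' @param standardize_data Standardize (statistics kept for prediction).
#' @param variance_kept PCA retention rule (see [pca_project()]).
#' @return A `vada_baseline` object with a [predict()] method.
#' @export
fit_baseline <- function(train, method = c("gmm-mm", "vade-mm", "vae-gmm-mm"),
                         K, D = NULL, working = "exchangeable",
                         link = "identity", epochs = 500L, lr = 1e-3,
                         seed = 1L, standardize_data = TRUE,
                         variance_kept = 0.9999) {
  method <- match.arg(method)
  stats <- NULL
  if (standardize_data) {
    sd_ <- standardize(train); train <- sd_$data; stats <- sd_$stats
  }
  enc_fit <- NULL; gmm <- NULL
  if (method == "vade-mm") {
    enc_fit <- fit_vade(train, D, K, epochs = epochs, lr = lr, seed = seed)
    E <- apply_x_encoder(enc_fit$nets, train$X)$mu
    probs <- vade_obs_probs(enc_fit, train$X)
  } else if (method == "vae-gmm-mm") {
    enc_fit <- fit_vae(train, D, epochs = epochs, lr = lr, seed = seed)
    E <- apply_x_encoder(enc_fit$nets, train$X)$mu
    gmm <- fit_gmm(E, K)
    probs <- gmm_probs(gmm, E)
  } else {
    E <- train$X
    gmm <- fit_gmm(E, K)
    probs <- gmm_probs(gmm, E)
  }
  labels <- merge_subject_clusters(probs, rep(train$subject_ids, each = train$L))
  pca <- pca_project(E, variance_kept)
  gee <- fit_cluster_gee(pca$scores, train$y, labels, K,
                         working = working, link = link)
  structure(list(method = method, K = K, D = D, working = working, link = link,
                 stats = stats, enc_fit = enc_fit, gmm = gmm, pca = pca,
                 gee = gee, labels = labels),
            class = "vada_baseline")
}

#' @export
predict.vada_baseline <- function(object, newdata, ...) {
  data <- if (!is.null(object$stats)) standardize(newdata, object$stats)$data else newdata
  if (object$method == "gmm-mm") {
    E <- data$X
    probs <- gmm_probs(object$gmm, E)
  } else if (object$method == "vae-gmm-mm") {
    E <- apply_x_encoder(object$enc_fit$nets, data$X)$mu
    probs <- gmm_probs(object$gmm, E)
  } else {
    E <- apply_x_encoder(object$enc_fit$nets, data$X)$mu
    probs <- vade_obs_probs(object$enc_fit, data$X)
  }
  labels <- merge_subject_clusters(probs, rep(data$subject_ids, each = data$L))
  scores <- pca_apply(object$pca, E)
  Xd <- cbind(1, scores)
  N <- data$N; L <- data$L
  y_hat <- matrix(NA_real_, N, L)
  for (k in seq_len(object$K)) {
    subj <- which(labels == k)
    if (!length(subj)) next
    fitk <- object$gee[[k]]
    if (is.null(fitk)) {  # cluster empty at training: fall back to pooled mean
      y_hat[subj, ] <- mean(data$y)
      next
    }
    rows <- as.numeric(t(outer(subj - 1L, seq_len(L), function(a, b) a * L + b)))
    y_hat[subj, ] <- matrix(stats::predict(fitk, Xd[rows, , drop = FALSE]),
                            length(subj), L, byrow = TRUE)
  }
  list(y_hat = y_hat, labels = labels, probs_obs = probs)
}
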