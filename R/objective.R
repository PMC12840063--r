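#' Variational posterior summaries for a dataset
#'
#' Runs the two encoders over a dataset and collects the per-subject
#' posterior parameters: `mu_z`/`sigma2_z` ((N*L) x D, subject-major rows)
#' from the X-encoder and `mu_u`/`sigma2_u` (N x L) from the Y-encoder.
#'
#' @param nets A `vada_nets` bundle.
#' @param data A [vada_data()] object.
#' @return A `vada_state` list.
#' @export
variational_state <- function(nets, data) {
  ez <- apply_x_encoder(nets, data$X)
  eu <- apply_y_encoder(nets, data$y)
  structure(list(mu_z = ez$mu, sigma2_z = ez$sigma2,
                 mu_u = eu$mu, sigma2_u = eu$sigma2,
                 N = data$N, L = data$L, D = ncol(ez$mu)),
            class = "vada_state")
}

# shared noise-drawing convention so the numeric and tape paths see
# identical reparameterization draws for a given seed
draw_eps <- function(N, L, D, M, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(M), function(m) {
    list(z = matrix(stats::rnorm(N * L * D), N * L, D),
         u = matrix(stats::rnorm(N * L), N, L))
  })
}

#' Reparameterized samples of the latent variables
#'
#' Draws `M` samples `u = mu_u + sd_u * eps`, `z = mu_z + sd_z * eps` with
#' standard-normal noise.
#'
#' @param state A [variational_state()] object.
#' @param M Number of Monte-Carlo samples.
#' @param seed Integer seed.
#' @return A list of `M` elements, each with `u` (N x L) and `Z`
#'   ((N*L) x D).
#' @export
reparameterized_samples <- function(state, M = 1L, seed = 1L) {
  stopifnot(M >= 1L)
  eps <- draw_eps(state$N, state$L, state$D, M, seed)
  lapply(eps, function(e) {
    list(u = state$mu_u + sqrt(state$sigma2_u) * e$u,
         Z = state$mu_z + sqrt(state$sigma2_z) * e$z)
  })
}

#' Monte-Carlo reconstruction terms
#'
#' Decodes each latent sample and averages the per-subject log-densities of
#' the observed outcomes and features. For real outcomes and continuous
#' features these are Gaussian log-densities with decoder mean and variance
#' heads; for categorical ones, log-probabilities of the observed category
#' (for a binary outcome this is the negative cross-entropy).
#'
#' @param data A [vada_data()] object.
#' @param nets A `vada_nets` bundle.
#' @param samples Output of [reparameterized_samples()] for this data.
#' @return A list with scalars `recon_y` and `recon_x` (per-subject batch
#'   means).
#' @export
reconstruction_terms <- function(data, nets, samples) {
  meta <- net_meta(nets)
  N <- data$N; L <- data$L
  ry <- 0; rx <- 0
  for (s in samples) {
    dy <- apply_y_decoder(nets, s$u)
    if (!meta$y_cat) {
      ry <- ry + sum(gauss_logdens(data$y, dy$mu, dy$sigma2))
    } else {
      for (l in seq_len(L)) {
        ry <- ry + sum(log(dy$prob[[l]][cbind(seq_len(N), data$y[, l])]))
      }
    }
    dx <- apply_x_decoder(nets, s$Z)
    if (length(meta$con_idx)) {
      rx <- rx + sum(gauss_logdens(data$X[, meta$con_idx, drop = FALSE], dx$mu, dx$sigma2))
    }
    if (length(meta$cat_idx)) {
      for (j in seq_along(meta$cat_idx)) {
        rx <- rx + sum(log(dx$prob[[j]][cbind(seq_len(N * L), data$X[, meta$cat_idx[j]])]))
      }
    }
  }
  M <- length(samples)
  list(recon_y = ry / (M * N), recon_x = rx / (M * N))
}

#' Monte-Carlo posterior over clusters
#'
#' Approximates q(c | y, X) per subject by averaging the responsibilities
#' h(u, Z, c; H) over the latent samples.
#'
#' @param samples Output of [reparameterized_samples()].
#' @param params A [vada_params()] object.
#' @return N x K matrix; rows sum to 1.
#' @export
mixture_posterior <- function(samples, params) {
  acc <- NULL
  for (s in samples) {
    lw <- log_h_terms(s$u, s$Z, params)
    m <- apply(lw, 1L, max)
    w <- exp(lw - m)
    h <- w / rowSums(w)
    acc <- if (is.null(acc)) h else acc + h
  }
  acc / length(samples)
}

#' Analytic KL term of the variational objective
#'
#' Evaluates the closed-form expression for the KL divergence between the
#' mean-field posterior q(u, Z, c | y, X) and the prior p(u, Z, c), given
#' the cluster posterior `pi_tilde`. The expression is evaluated exactly as
#' assembled in the objective; it equals the true KL plus the constant
#' (L + L*D)/2, which does not affect gradients (see the package vignette).
#'
#' @param state A [variational_state()] object.
#' @param pi_tilde N x K matrix of cluster posteriors (e.g. from
#'   [mixture_posterior()]).
#' @param params A [vada_params()] object.
#' @return Scalar: per-subject KL (printed form), averaged over subjects.
#' @export
kl_term <- function(state, pi_tilde, params) {
  mean(kl_term_subjects(state, pi_tilde, params))
}

kl_term_subjects <- function(state, pi_tilde, params) {
  N <- state$N; L <- state$L; D <- state$D; K <- params$K
  if (any(state$sigma2_z <= 0) || any(state$sigma2_u <= 0)) {
    stop("variance underflow in variational state")
  }
  pi_tilde <- as_mat(pi_tilde)
  mu_u_v <- as.numeric(t(state$mu_u))      # (N*L), subject-major
  s2_u_v <- as.numeric(t(state$sigma2_u))
  grp <- rep(seq_len(N), each = L)
  A <- matrix(0, N, K)  # u-part + z-part per cluster
  for (k in seq_len(K)) {
    bk <- params$beta[k, ]
    m <- params$beta0[k] + as.numeric(state$mu_z %*% bk)
    quad_u <- (mu_u_v - m)^2 + s2_u_v + as.numeric(state$sigma2_z %*% (bk^2))
    a_u <- log(params$sigma2_u[k]) + quad_u / params$sigma2_u[k]
    mu_k <- matrix(params$mu[k, ], N * L, D, byrow = TRUE)
    s2_k <- matrix(params$sigma2[k, ], N * L, D, byrow = TRUE)
    a_z <- rowSums(log(s2_k) + ((state$mu_z - mu_k)^2 + state$sigma2_z) / s2_k)
    A[, k] <- as.numeric(rowsum(a_u + a_z, grp, reorder = FALSE))
  }
  lpt <- log(pmax(pi_tilde, 1e-300))
  ent <- rowSums(pi_tilde * lpt)
  cross <- rowSums(pi_tilde * matrix(log(params$pi), N, K, byrow = TRUE))
  0.5 * rowSums(pi_tilde * A) - cross + ent -
    0.5 * as.numeric(rowsum(log(s2_u_v), grp, reorder = FALSE)) -
    0.5 * as.numeric(rowsum(rowSums(log(state$sigma2_z)), grp, reorder = FALSE))
}

#' Evidence lower bound of the model on a dataset
#'
#' Assembles the per-subject ELBO = recon_y + recon_x - kl from its parts,
#' using `M` reparameterized Monte-Carlo samples.
#'
#' @param data A [vada_data()] object.
#' @param nets A `vada_nets` bundle.
#' @param params A [vada_params()] object.
#' @param M Number of Monte-Carlo samples (training default 1).
#' @param seed Integer seed for the noise draws.
#' @return A `vada_elbo` list with `recon_y`, `recon_x`, `kl`, `elbo`.
#' @export
elbo <- function(data, nets, params, M = 1L, seed = 1L) {
  state <- variational_state(nets, data)
  samples <- reparameterized_samples(state, M, seed)
  rec <- reconstruction_terms(data, nets, samples)
  pt <- mixture_posterior(samples, params)
  kl <- kl_term(state, pt, params)
  structure(list(recon_y = rec$recon_y, recon_x = rec$recon_x, kl = kl,
                 elbo = rec$recon_y + rec$recon_x - kl, pi_tilde = pt),
            class = "vada_elbo")
}

#' @export
print.vada_elbo <- function(x, ...) {
  cat(sprintf("<vada_elbo> elbo %.4f = recon_y %.4f + recon_x %.4f - kl %.4f\n",
              x$elbo, x$recon_y, x$recon_x, x$kl))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Tape (differentiable) ELBO used by the trainer. Mixture parameters enter
# unconstrained: pi via logits, variances via logs. Returns the elbo node
# plus component values; gradients flow through pi_tilde into H and the
# encoders (no stop-gradient).
# ---------------------------------------------------------------------------

# unconstrained parameterization of vada_params
params_to_uncon <- function(params) {
  list(pi_logit = matrix(log(params$pi), 1L),
       mu = params$mu,
       log_sigma2 = log(params$sigma2),
       beta0 = matrix(params$beta0, 1L),
       beta = params$beta,
       log_sigma2_u = matrix(log(params$sigma2_u), 1L))
}

uncon_to_params <- function(un) {
  pl <- as.numeric(un$pi_logit)
  pi <- exp(pl - max(pl)); pi <- pi / sum(pi)
  vada_params(pi = pi, mu = un$mu,
              sigma2 = pmax(exp(un$log_sigma2), VAR_FLOOR),
              beta0 = as.numeric(un$beta0), beta = un$beta,
              sigma2_u = pmax(exp(as.numeric(un$log_sigma2_u)), VAR_FLOOR))
}

# gaussian log-density node, rowwise: const data matrix x vs nodes mu, lv
ad_gauss_ld <- function(tp, x_const, mu, lv) {
  d <- ad_sub(tp, ad_const(tp, x_const), mu)
  q <- ad_mul(tp, ad_sqr(tp, d), ad_exp(tp, ad_neg(tp, lv)))
  ad_scale(tp, ad_addc(tp, ad_add(tp, lv, q), LOG2PI), -0.5)
}

# forward through a dense net on the tape; returns node list of linear
# heads. x may be a node or a constant matrix.
ad_dense <- function(tp, w, prefix, x, activation, heads) {
  h <- ad_dense_layer(tp, x, w[[paste0(prefix, "W1")]], w[[paste0(prefix, "b1")]],
                      activation)
  out <- list()
  for (hn in heads) {
    out[[hn]] <- ad_dense_layer(tp, h, w[[paste0(prefix, "W_", hn)]],
                                w[[paste0(prefix, "b_", hn)]], "linear")
  }
  out
}

ad_getcol <- function(tape, a, j) {
  ad_node(tape, a$value[, j, drop = FALSE], list(a), function(g) {
    z <- matrix(0, nrow(a$value), ncol(a$value))
    z[, j] <- g
    list(z)
  })
}

# Build the full differentiable ELBO for a batch.
#   wts:   named list of weight nodes (same names as vada_nets entries)
#   un:    list of unconstrained mixture parameter nodes
#   batch: vada_data subset
#   eps:   list of M noise draws (draw_eps format)
# Returns list of nodes: elbo, recon_y, recon_x, kl, pi_tilde.
elbo_tape <- function(tp, wts, un, batch, eps, meta) {
  N <- batch$N; L <- batch$L; D <- meta$D
  K <- ncol(un$pi_logit$value)
  act <- meta$arch$activation
  # subject-major stacking index: element (n,l) of an N x L matrix sits at
  # column-major position (l-1)*N + n; stacked row r = (n-1)*L + l
  nl <- expand.grid(l = seq_len(L), n = seq_len(N))
  stack_idx <- (nl$l - 1L) * N + nl$n
  agg <- aggregate_matrix(N, L)

  Xe <- expand_features(batch$X, meta)
  enc <- ad_dense(tp, wts, "xe_", Xe, act, c("m", "v"))
  mu_z <- enc$m
  lv_z <- ad_clamp_min(tp, enc$v, LOGV_FLOOR)

  ye <- ad_dense(tp, wts, "ye_", y_enc_input(batch$y, meta), act, c("m", "v"))
  mu_u <- ye$m
  lv_u <- ad_clamp_min(tp, ye$v, LOGV_FLOOR)

  log_pi <- ad_sub(tp, un$pi_logit, ad_lse_rows(tp, un$pi_logit))  # 1 x K

  recon_y_acc <- NULL; recon_x_acc <- NULL; h_acc <- NULL
  xd_heads <- c(if (length(meta$con_idx)) c("m", "v"),
                if (length(meta$cat_idx)) paste0("c", seq_along(meta$cat_idx)))
  yd_heads <- if (meta$y_cat) "c" else c("m", "v")

  for (m in seq_along(eps)) {
    z <- ad_reparam(tp, mu_z, enc$v, eps[[m]]$z)
    u <- ad_reparam(tp, mu_u, ye$v, eps[[m]]$u)

    # reconstruction of x
    dec <- ad_dense(tp, wts, "xd_", z, act, xd_heads)
    rx_sum <- NULL
    if (length(meta$con_idx)) {
      rx_sum <- ad_gauss_recon(tp, batch$X[, meta$con_idx, drop = FALSE],
                               dec$m, dec$v)
    }
    if (length(meta$cat_idx)) {
      for (j in seq_along(meta$cat_idx)) {
        logits <- dec[[paste0("c", j)]]
        lp <- ad_sub(tp, logits, ad_lse_rows(tp, logits))
        oh <- matrix(0, N * L, meta$cat_G[j])
        oh[cbind(seq_len(N * L), batch$X[, meta$cat_idx[j]])] <- 1
        term <- ad_sum(tp, ad_mul(tp, lp, ad_const(tp, oh)))
        rx_sum <- if (is.null(rx_sum)) term else ad_add(tp, rx_sum, term)
      }
    }
    rx_m <- ad_scale(tp, rx_sum, 1 / N)
    recon_x_acc <- if (is.null(recon_x_acc)) rx_m else ad_add(tp, recon_x_acc, rx_m)

    # reconstruction of y (decoder consumes the whole u vector)
    dy <- ad_dense(tp, wts, "yd_", u, act, yd_heads)
    if (!meta$y_cat) {
      ry_m <- ad_scale(tp, ad_gauss_recon(tp, batch$y, dy$m, dy$v), 1 / N)
    } else {
      G <- meta$G_y
      ry_rows <- NULL
      for (l in seq_len(L)) {
        logits <- ad_node(tp, dy$c$value[, (l - 1L) * G + seq_len(G), drop = FALSE],
                          list(dy$c), local({
                            l0 <- l
                            function(g) {
                              zfull <- matrix(0, N, L * G)
                              zfull[, (l0 - 1L) * G + seq_len(G)] <- g
                              list(zfull)
                            }
                          }))
        lp <- ad_sub(tp, logits, ad_lse_rows(tp, logits))
        oh <- matrix(0, N, G); oh[cbind(seq_len(N), batch$y[, l])] <- 1
        term <- ad_rowsum(tp, ad_mul(tp, lp, ad_const(tp, oh)))
        ry_rows <- if (is.null(ry_rows)) term else ad_add(tp, ry_rows, term)
      }
      ry_m <- ad_scale(tp, ad_sum(tp, ry_rows), 1 / N)
    }
    recon_y_acc <- if (is.null(recon_y_acc)) ry_m else ad_add(tp, recon_y_acc, ry_m)

    # responsibilities of this sample, all K components at once:
    # log p(u|Z,k) and log p(Z|k) as quadratic forms in (BL x K) blocks
    u_bl <- ad_permute(tp, u, stack_idx, N * L, 1L)
    inv_u <- ad_exp(tp, ad_neg(tp, un$log_sigma2_u))        # 1 x K
    m_u <- ad_add(tp, ad_mm(tp, z, ad_t(tp, un$beta)), un$beta0)  # BL x K
    du2 <- ad_sqr(tp, ad_sub(tp, m_u, u_bl))                # (u - m)^2, BL x K
    ld_u <- ad_scale(tp, ad_addc(tp, ad_add(tp, ad_mul(tp, du2, inv_u),
                                            un$log_sigma2_u), LOG2PI), -0.5)
    inv_z <- ad_exp(tp, ad_neg(tp, un$log_sigma2))          # K x D
    # sum_d (z_d - mu_kd)^2 / s2_kd = z^2 inv' - 2 z (mu*inv)' + rowconst
    mu_inv <- ad_mul(tp, un$mu, inv_z)
    cz <- ad_rowsum(tp, ad_add(tp, ad_mul(tp, ad_sqr(tp, un$mu), inv_z),
                               un$log_sigma2))              # K x 1
    quad_z <- ad_add(tp,
      ad_sub(tp, ad_mm(tp, ad_sqr(tp, z), ad_t(tp, inv_z)),
             ad_scale(tp, ad_mm(tp, z, ad_t(tp, mu_inv)), 2)),
      ad_t(tp, cz))                                          # BL x K
    ld_z <- ad_scale(tp, ad_addc(tp, quad_z, D * LOG2PI), -0.5)
    per_subj <- ad_mm(tp, ad_const(tp, agg), ad_add(tp, ld_u, ld_z))  # N x K
    log_h <- ad_add(tp, per_subj, log_pi)
    h <- ad_softmax_rows(tp, log_h)
    h_acc <- if (is.null(h_acc)) h else ad_add(tp, h_acc, h)
  }
  M <- length(eps)
  recon_y <- ad_scale(tp, recon_y_acc, 1 / M)
  recon_x <- ad_scale(tp, recon_x_acc, 1 / M)
  pi_tilde <- ad_scale(tp, h_acc, 1 / M)

  # analytic KL (printed form) with the variational means/variances
  s2_z <- ad_exp(tp, lv_z)
  mu_u_bl <- ad_permute(tp, mu_u, stack_idx, N * L, 1L)
  s2_u_bl <- ad_permute(tp, ad_exp(tp, lv_u), stack_idx, N * L, 1L)
  inv_u <- ad_exp(tp, ad_neg(tp, un$log_sigma2_u))           # 1 x K
  m_mu <- ad_add(tp, ad_mm(tp, mu_z, ad_t(tp, un$beta)), un$beta0)  # BL x K
  quad_u <- ad_add(tp, ad_add(tp, ad_sqr(tp, ad_sub(tp, m_mu, mu_u_bl)),
                              s2_u_bl),
                   ad_mm(tp, s2_z, ad_t(tp, ad_sqr(tp, un$beta))))
  a_u <- ad_add(tp, ad_mul(tp, quad_u, inv_u), un$log_sigma2_u)    # BL x K
  inv_z <- ad_exp(tp, ad_neg(tp, un$log_sigma2))             # K x D
  mu_inv <- ad_mul(tp, un$mu, inv_z)
  cz <- ad_rowsum(tp, ad_add(tp, ad_mul(tp, ad_sqr(tp, un$mu), inv_z),
                             un$log_sigma2))                 # K x 1
  a_z <- ad_add(tp,
    ad_sub(tp, ad_mm(tp, ad_add(tp, ad_sqr(tp, mu_z), s2_z), ad_t(tp, inv_z)),
           ad_scale(tp, ad_mm(tp, mu_z, ad_t(tp, mu_inv)), 2)),
    ad_t(tp, cz))                                            # BL x K
  A <- ad_mm(tp, ad_const(tp, agg), ad_add(tp, a_u, a_z))    # N x K
  kl_mix <- ad_scale(tp, ad_rowsum(tp, ad_mul(tp, pi_tilde, A)), 0.5)
  cross <- ad_rowsum(tp, ad_mul(tp, pi_tilde, log_pi))      # row-broadcast
  lpt <- ad_log(tp, ad_clamp_min(tp, pi_tilde, 1e-300))
  ent <- ad_rowsum(tp, ad_mul(tp, pi_tilde, lpt))
  ent_u <- ad_scale(tp, ad_rowsum(tp, lv_u), 0.5)           # N x 1
  ent_z <- ad_scale(tp, ad_mm(tp, ad_const(tp, agg), ad_rowsum(tp, lv_z)), 0.5)
  kl_subj <- ad_sub(tp, ad_sub(tp, ad_add(tp, ad_sub(tp, kl_mix, cross), ent), ent_u), ent_z)
  kl <- ad_scale(tp, ad_sum(tp, kl_subj), 1 / N)

  elbo_node <- ad_sub(tp, ad_add(tp, recon_y, recon_x), kl)
  list(elbo = elbo_node, recon_y = recon_y, recon_x = recon_x, kl = kl,
       pi_tilde = pi_tilde)
}

# N x (N*L) summing matrix over the L rows of each subject
aggregate_matrix <- function(N, L) {
  m <- matrix(0, N, N * L)
  m[cbind(rep(seq_len(N), each = L), seq_len(N * L))] <- 1
  m
}
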