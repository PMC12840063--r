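#' Mixture-prior and marginal-model parameters
#'
#' Container for the generative parameters H: mixture weights `pi`,
#' component means `mu` (K x D) and diagonal variances `sigma2` (K x D) of
#' the latent prior, and per-cluster marginal-model parameters — intercepts
#' `beta0` (K), effects `beta` (K x D) and residual variances `sigma2_u`
#' (K). The latent pure outcome of measurement l in cluster k is
#' \eqn{u_l ~ N(\beta_{k0} + z_l' \beta_k, \sigma^2_{u,k})}.
#'
#' @param pi Length-K simplex of cluster weights.
#' @param mu K x D matrix of component means.
#' @param sigma2 K x D matrix of positive component variances.
#' @param beta0 Length-K intercepts.
#' @param beta K x D matrix of marginal effects.
#' @param sigma2_u Length-K positive residual variances.
#' @return A `vada_params` object.
#' @export
vada_params <- function(pi, mu, sigma2, beta0, beta, sigma2_u) {
  mu <- as_mat(mu); sigma2 <- as_mat(sigma2); beta <- as_mat(beta)
  K <- length(pi); D <- ncol(mu)
  stopifnot(nrow(mu) == K, all(dim(sigma2) == c(K, D)),
            length(beta0) == K, all(dim(beta) == c(K, D)),
            length(sigma2_u) == K)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be a simplex (nonnegative, summing to 1)")
  }
  if (any(sigma2 <= 0) || any(sigma2_u <= 0)) stop("variances must be positive")
  structure(list(pi = as.numeric(pi), mu = mu, sigma2 = sigma2,
                 beta0 = as.numeric(beta0), beta = beta,
                 sigma2_u = as.numeric(sigma2_u), K = K, D = D),
            class = "vada_params")
}

#' Longitudinal dataset container
#'
#' Internal array representation of a balanced longitudinal dataset:
#' `N` subjects, each with exactly `L` measurements of `P` features and one
#' outcome. Rows of `X` are observations in subject-major order (subject 1
#' measurements 1..L, then subject 2, ...). Categorical feature columns and
#' categorical outcomes hold 1-based integer codes.
#'
#' @param subject_ids Length-N vector of subject identifiers.
#' @param X (N*L) x P numeric matrix of features.
#' @param y N x L outcome matrix.
#' @param feature_kinds List of length P; each element
#'   `list(kind = "continuous")` or `list(kind = "categorical", levels = ...)`.
#' @param outcome_kind `"real"` or `list(kind = "categorical", levels = ...)`.
#' @param truth Optional list with `c_true` (length N), `Z_true`
#'   ((N*L) x D matrix) and `u_true` (N x L); populated by the simulators
#'   only.
#' @return A `vada_data` object.
#' @export
vada_data <- function(subject_ids, X, y, feature_kinds,
                      outcome_kind = "real", truth = NULL) {
  N <- length(subject_ids)
  y <- as_mat(y)
  L <- ncol(y)
  stopifnot(L >= 1L, nrow(y) == N, nrow(X) == N * L,
            length(feature_kinds) == ncol(X))
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  for (p in seq_along(feature_kinds)) {
    fk <- feature_kinds[[p]]
    if (fk$kind == "categorical") {
      v <- X[, p]
      if (any(v != round(v)) || any(v < 1) || any(v > length(fk$levels))) {
        stop("categorical feature ", p, " has codes outside 1..", length(fk$levels))
      }
    }
  }
  if (is.list(outcome_kind) && identical(outcome_kind$kind, "categorical")) {
    G <- length(outcome_kind$levels)
    if (any(y != round(y)) || any(y < 1) || any(y > G)) {
      stop("categorical outcome has codes outside 1..", G)
    }
  }
  structure(list(subject_ids = subject_ids, X = X, y = y,
                 feature_kinds = feature_kinds, outcome_kind = outcome_kind,
                 truth = truth, N = N, L = L, P = ncol(X)),
            class = "vada_data")
}

#' @export
print.vada_data <- function(x, ...) {
  cat("<vada_data> ", x$N, " subjects x ", x$L, " measurements x ",
      x$P, " features; outcome ",
      if (is.list(x$outcome_kind)) "categorical" else "real",
      if (!is.null(x$truth)) "; ground truth attached" else "", "\n", sep = "")
  invisible(x)
}

data_spec <- function(data, D) {
  list(D = D, L = data$L, feature_kinds = data$feature_kinds,
       outcome_kind = data$outcome_kind)
}

LOG2PI <- log(2 * pi)

# rowwise Gaussian log-density sums: x, mu, sigma2 conformable matrices
gauss_logdens <- function(x, mu, sigma2) {
  -0.5 * (LOG2PI + log(sigma2) + (x - mu)^2 / sigma2)
}

#' Cluster responsibilities h(u, Z, c; H)
#'
#' Posterior probability of each cluster given the latent pure outcomes `u`
#' and latent representations `Z` of one subject:
#' \deqn{h(u,Z,k;H) \propto p(u|Z,k)\,p(Z|k)\,\pi_k}
#' with \eqn{p(u|Z,k)=\prod_l N(u_l;\beta_{k0}+z_l'\beta_k,\sigma^2_{u,k})}
#' and \eqn{p(Z|k)=\prod_l N(z_l;\mu_k,diag\,\sigma^2_k)}. Computed in log
#' space with max-subtraction.
#'
#' @param u Length-L numeric vector of pure outcomes.
#' @param Z L x D matrix of latent representations.
#' @param params A [vada_params()] object.
#' @return Length-K probability vector summing to 1.
#' @export
responsibilities <- function(u, Z, params) {
  Z <- as_mat(Z)
  lw <- log_h_terms(matrix(u, nrow = 1L), Z, params, n_subj = 1L)
  if (any(!is.finite(lw))) {
    stop("non-finite component density in responsibilities (component ",
         paste(which(!is.finite(lw)), collapse = ","), "); variance underflow?")
  }
  m <- max(lw)
  w <- exp(lw - m)
  as.numeric(w / sum(w))
}

# Batched unnormalized log responsibilities. u: N x L, Z: (N*L) x D in
# subject-major row order. Returns N x K matrix of
# log pi_k + log p(u|Z,k) + log p(Z|k).
log_h_terms <- function(u, Z, params, n_subj = nrow(u)) {
  N <- n_subj; L <- ncol(u); K <- params$K; D <- params$D
  stopifnot(nrow(Z) == N * L, ncol(Z) == D)
  out <- matrix(0, N, K)
  uv <- as.numeric(t(u))  # stacked subject-major, length N*L
  grp <- rep(seq_len(N), each = L)
  for (k in seq_len(K)) {
    m_u <- params$beta0[k] + as.numeric(Z %*% params$beta[k, ])
    ld_u <- gauss_logdens(uv, m_u, params$sigma2_u[k])
    ld_z <- rowSums(gauss_logdens(Z,
                                  matrix(params$mu[k, ], N * L, D, byrow = TRUE),
                                  matrix(params$sigma2[k, ], N * L, D, byrow = TRUE)))
    per_obs <- ld_u + ld_z
    out[, k] <- log(params$pi[k]) +
      as.numeric(rowsum(per_obs, grp, reorder = FALSE))
  }
  out
}

#' Complete-data log-likelihood of one subject
#'
#' Evaluates \eqn{\log p(y,u,X,Z,c)} for one subject under the generative
#' process: \eqn{\log p(y|u) + \sum_l[\log p(u_l|z_l,c) + \log p(x_l|z_l) +
#' \log p(z_l|c)] + \log \pi_c}.
#'
#' @param y Length-L outcome vector (or categorical codes).
#' @param u Length-L pure-outcome vector.
#' @param X L x P feature matrix for the subject.
#' @param Z L x D latent matrix.
#' @param c Integer cluster label in 1..K.
#' @param params A [vada_params()] object.
#' @param nets A `vada_nets` bundle supplying the decoders.
#' @return Scalar log-likelihood.
#' @export
complete_data_loglik <- function(y, u, X, Z, c, params, nets) {
  meta <- net_meta(nets)
  Z <- as_mat(Z); X <- as_mat(X)
  L <- nrow(Z)
  stopifnot(length(y) == L, length(u) == L, nrow(X) == L,
            c >= 1L, c <= params$K)
  # y | u
  dy <- apply_y_decoder(nets, matrix(u, nrow = 1L))
  if (!meta$y_cat) {
    ll_y <- sum(gauss_logdens(matrix(y, nrow = 1L), dy$mu, dy$sigma2))
  } else {
    ll_y <- sum(vapply(seq_len(L), function(l) log(dy$prob[[l]][1L, y[l]]), 0))
  }
  # x | z
  dx <- apply_x_decoder(nets, Z)
  ll_x <- 0
  if (length(meta$con_idx)) {
    ll_x <- ll_x + sum(gauss_logdens(X[, meta$con_idx, drop = FALSE], dx$mu, dx$sigma2))
  }
  if (length(meta$cat_idx)) {
    for (j in seq_along(meta$cat_idx)) {
      v <- X[, meta$cat_idx[j]]
      if (any(v < 1 | v > meta$cat_G[j])) stop("category index out of range in feature ", meta$cat_idx[j])
      ll_x <- ll_x + sum(log(dx$prob[[j]][cbind(seq_len(L), v)]))
    }
  }
  # u | z, c
  m_u <- params$beta0[c] + as.numeric(Z %*% params$beta[c, ])
  ll_u <- sum(gauss_logdens(u, m_u, params$sigma2_u[c]))
  # z | c and c
  ll_z <- sum(gauss_logdens(Z, matrix(params$mu[c, ], L, params$D, byrow = TRUE),
                            matrix(params$sigma2[c, ], L, params$D, byrow = TRUE)))
  ll_y + ll_x + ll_u + ll_z + log(params$pi[c])
}

#' Sample from the generative process
#'
#' Draws subjects from the full generative model: cluster label
#' \eqn{c ~ Cat(\pi)}; latents \eqn{z_l ~ N(\mu_c, diag\,\sigma^2_c)};
#' features from the X-decoder heads; pure outcomes
#' \eqn{u_l ~ N(\beta_{c0}+z_l'\beta_c, \sigma^2_{u,c})}; outcomes from the
#' Y-decoder applied to the whole vector u.
#'
#' @param params A [vada_params()] object.
#' @param nets A `vada_nets` bundle (dimensions must match `params`).
#' @param n_subjects Number of subjects to draw.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A [vada_data()] object with the `truth` fields filled.
#' @export
sample_generative <- function(params, nets, n_subjects, seed = 1L) {
  meta <- net_meta(nets)
  if (meta$D != params$D) stop("latent dimension mismatch between nets (D=", meta$D,
                               ") and params (D=", params$D, ")")
  N <- as.integer(n_subjects); L <- meta$L; D <- meta$D; P <- meta$P
  if (N == 0L) {
    return(vada_data(character(0L), matrix(0, 0L, P), matrix(0, 0L, L),
                     feature_kinds_from_meta(meta), meta$outcome_kind,
                     truth = list(c_true = integer(0L),
                                  Z_true = matrix(0, 0L, D),
                                  u_true = matrix(0, 0L, L))))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  c_true <- sample.int(params$K, N, replace = TRUE, prob = params$pi)
  cl_obs <- rep(c_true, each = L)
  Z <- params$mu[cl_obs, , drop = FALSE] +
    sqrt(params$sigma2[cl_obs, , drop = FALSE]) * matrix(stats::rnorm(N * L * D), N * L, D)
  dx <- apply_x_decoder(nets, Z)
  X <- matrix(0, N * L, P)
  if (length(meta$con_idx)) {
    X[, meta$con_idx] <- dx$mu + sqrt(dx$sigma2) * matrix(stats::rnorm(N * L * length(meta$con_idx)),
                                                          N * L, length(meta$con_idx))
  }
  if (length(meta$cat_idx)) {
    for (j in seq_along(meta$cat_idx)) {
      pr <- dx$prob[[j]]
      X[, meta$cat_idx[j]] <- apply(pr, 1L, function(p) sample.int(length(p), 1L, prob = p))
    }
  }
  m_u <- params$beta0[cl_obs] + rowSums(Z * params$beta[cl_obs, , drop = FALSE])
  uv <- m_u + sqrt(params$sigma2_u[cl_obs]) * stats::rnorm(N * L)
  u <- matrix(uv, N, L, byrow = TRUE)
  dy <- apply_y_decoder(nets, u)
  if (!meta$y_cat) {
    y <- dy$mu + sqrt(dy$sigma2) * matrix(stats::rnorm(N * L), N, L)
  } else {
    y <- matrix(0L, N, L)
    for (l in seq_len(L)) {
      pr <- dy$prob[[l]]
      y[, l] <- apply(pr, 1L, function(p) sample.int(length(p), 1L, prob = p))
    }
  }
  vada_data(paste0("s", seq_len(N)), X, y, feature_kinds_from_meta(meta),
            meta$outcome_kind,
            truth = list(c_true = c_true, Z_true = Z, u_true = u))
}

feature_kinds_from_meta <- function(meta) {
  fk <- vector("list", meta$P)
  for (p in meta$con_idx) fk[[p]] <- list(kind = "continuous")
  for (j in seq_along(meta$cat_idx)) {
    fk[[meta$cat_idx[j]]] <- list(kind = "categorical",
                                  levels = seq_len(meta$cat_G[j]))
  }
  fk
}
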