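#' Fit a marginal model by generalized estimating equations
#'
#' Solves the GEE for a population-averaged regression of a longitudinal
#' outcome on covariates under a working within-subject correlation
#' structure: independence (MM0), AR-1 (MM1) or exchangeable (MM2). AR-1
#' and exchangeable coincide when there are two measurements per subject.
#' Supports the identity link (Gaussian variance) and the logit link
#' (binomial variance). Subjects must be balanced (equal numbers of
#' measurements).
#'
#' @param y Numeric response vector (0/1 for the logit link), one entry per
#'   observation.
#' @param X Design matrix (no intercept column is added; include one if
#'   wanted).
#' @param id Subject identifier per observation; observations of a subject
#'   must be contiguous and time-ordered.
#' @param working `"independence"`, `"ar1"` or `"exchangeable"`.
#' @param link `"identity"` or `"logit"`.
#' @param max_iter,tol Fisher-scoring controls.
#' @return A `vada_gee` object with `coef`, `alpha` (estimated working
#'   correlation parameter), `phi` (dispersion), `working`, `link`.
#' @export
gee_fit <- function(y, X, id, working = "independence", link = "identity",
                    max_iter = 50L, tol = 1e-8) {
  working <- match.arg(working, c("independence", "ar1", "exchangeable"))
  link <- match.arg(link, c("identity", "logit"))
  X <- as_mat(X)
  stopifnot(length(y) == nrow(X), length(id) == length(y))
  id <- as.integer(factor(id, levels = unique(id)))
  L <- as.integer(table(id)[1L])
  if (!all(table(id) == L)) stop("unbalanced subjects are not supported")
  n_subj <- max(id)
  p <- ncol(X)

  linkinv <- if (link == "identity") identity else function(e) 1 / (1 + exp(-e))
  varfun <- if (link == "identity") function(mu) rep(1, length(mu)) else function(mu) mu * (1 - mu)
  dmu_deta <- if (link == "identity") function(mu) rep(1, length(mu)) else function(mu) mu * (1 - mu)

  # initialize at the independence GLM solution
  beta <- if (link == "identity") {
    stats::lm.fit(X, y)$coefficients
  } else {
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())$coefficients)
  }
  beta[!is.finite(beta)] <- 0
  alpha <- 0

  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- linkinv(eta)
    v <- pmax(varfun(mu), 1e-10)
    r <- (y - mu) / sqrt(v)
    phi <- sum(r^2) / (length(y) - p)
    if (working == "exchangeable" && L > 1L) {
      rm_ <- matrix(r, nrow = L)  # L x n_subj (subject-contiguous)
      num <- sum((colSums(rm_)^2 - colSums(rm_^2)) / 2)
      alpha <- num / (n_subj * L * (L - 1) / 2 * phi)
    } else if (working == "ar1" && L > 1L) {
      rm_ <- matrix(r, nrow = L)
      alpha <- sum(rm_[-L, , drop = FALSE] * rm_[-1L, , drop = FALSE]) /
        (n_subj * (L - 1) * phi)
    } else alpha <- 0
    alpha <- max(min(alpha, 0.99), -0.99)
    R <- working_corr(working, alpha, L)
    Ri <- solve(R)

    d <- dmu_deta(mu)
    lhs <- matrix(0, p, p); rhs <- numeric(p)
    for (i in seq_len(n_subj)) {
      rows <- ((i - 1L) * L + 1L):(i * L)
      Di <- X[rows, , drop = FALSE] * d[rows]
      Ai_half_inv <- 1 / sqrt(v[rows])
      Vi_inv <- (Ai_half_inv %o% Ai_half_inv) * Ri / phi
      W <- crossprod(Di, Vi_inv)
      lhs <- lhs + W %*% Di
      rhs <- rhs + as.numeric(W %*% (y[rows] - mu[rows]))
    }
    delta <- solve(lhs, rhs)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  structure(list(coef = as.numeric(beta), alpha = alpha, phi = phi,
                 working = working, link = link, L = L, iterations = it),
            class = "vada_gee")
}

working_corr <- function(working, alpha, L) {
  R <- diag(L)
  if (working == "exchangeable") {
    R[] <- alpha; diag(R) <- 1
  } else if (working == "ar1") {
    R <- alpha^abs(outer(seq_len(L), seq_len(L), "-"))
  }
  R
}

#' @export
predict.vada_gee <- function(object, newX, ...) {
  eta <- as.numeric(as_mat(newX) %*% object$coef)
  if (object$link == "identity") eta else 1 / (1 + exp(-eta))
}

#' @export
print.vada_gee <- function(x, ...) {
  cat("<vada_gee> ", x$working, " working correlation, ", x$link,
      " link; alpha=", round(x$alpha, 4), "\n", sep = "")
  invisible(x)
}

#' Fit cluster-specific marginal models
#'
#' One GEE per cluster on that cluster's subjects. Empty clusters are
#' dropped with a warning and excluded from prediction.
#'
#' @param scores Per-observation design matrix (subject-major rows), e.g.
#'   PCA scores; an intercept column is prepended internally.
#' @param y N x L outcome matrix.
#' @param labels Per-subject cluster labels in 1..K.
#' @param K Number of clusters.
#' @param working,link Passed to [gee_fit()].
#' @return List of length K of `vada_gee` fits (NULL for empty clusters).
#' @export
fit_cluster_gee <- function(scores, y, labels, K, working = "independence",
                            link = "identity") {
  N <- nrow(y); L <- ncol(y)
  stopifnot(nrow(scores) == N * L, length(labels) == N)
  Xd <- cbind(1, scores)
  fits <- vector("list", K)
  for (k in seq_len(K)) {
    subj <- which(labels == k)
    if (!length(subj)) {
      warning("cluster ", k, " is empty; dropped from the marginal models")
      next
    }
    rows <- as.numeric(t(outer(subj - 1L, seq_len(L), function(a, b) a * L + b)))
    fits[[k]] <- tryCatch(
      gee_fit(as.numeric(t(y))[rows], Xd[rows, , drop = FALSE],
              rep(subj, each = L), working = working, link = link),
      error = function(e) stop("GEE failed in cluster ", k, ": ", conditionMessage(e)))
  }
  fits
}
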