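#' Architecture configuration for the four function approximators
#'
#' The model uses four small dense networks: the X-encoder \eqn{g_z} (feature
#' vector to latent posterior), the X-decoder \eqn{f_x} (latent vector to
#' per-feature distribution parameters), the Y-encoder \eqn{g_u} (outcome
#' vector to pure-outcome posterior) and the Y-decoder \eqn{f_y}
#' (pure-outcome vector to outcome distribution parameters). Each is a
#' single-hidden-layer perceptron; variances are produced by a log-variance
#' head exponentiated (and floored at `1e-6`) at apply time, and categorical
#' heads produce simplexes through normalized exponentials.
#'
#' The Y-decoder consumes the whole length-`L` pure-outcome vector jointly;
#' it is never applied per measurement. This is what couples the repeated
#' measurements of a subject.
#'
#' @param hidden_x Hidden width of the X-encoder and X-decoder.
#' @param hidden_y Hidden width of the Y-encoder and Y-decoder.
#' @param activation Hidden activation, `"tanh"` (default) or `"relu"`.
#' @param init One of `"glorot"` (default) or `"zero"` (zeroes every weight
#'   and bias; useful for tests).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `vada_arch`.
#' @export
vada_arch <- function(hidden_x = 64L, hidden_y = 16L, activation = "tanh",
                      init = "glorot", seed = 1L) {
  stopifnot(hidden_x >= 1L, hidden_y >= 1L,
            activation %in% c("tanh", "relu"),
            init %in% c("glorot", "zero"))
  structure(list(hidden_x = as.integer(hidden_x), hidden_y = as.integer(hidden_y),
                 activation = activation, init = init, seed = as.integer(seed)),
            class = "vada_arch")
}

VAR_FLOOR <- 1e-6
LOGV_FLOOR <- log(1e-6)

glorot_mat <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

init_dense <- function(n_in, n_hidden, head_dims, init) {
  w <- list()
  mk <- function(fi, fo) if (init == "zero") matrix(0, fi, fo) else glorot_mat(fi, fo)
  w$W1 <- mk(n_in, n_hidden)
  w$b1 <- matrix(0, 1L, n_hidden)
  for (h in names(head_dims)) {
    w[[paste0("W_", h)]] <- mk(n_hidden, head_dims[[h]])
    w[[paste0("b_", h)]] <- matrix(0, 1L, head_dims[[h]])
  }
  w
}

#' Build the network bundle
#'
#' Instantiates the four networks for given data dimensions. Weights are
#' drawn by the configured scheme with the configured seed; no pretraining
#' is performed.
#'
#' @param arch A [vada_arch()] configuration.
#' @param spec A list with elements `D` (latent dimension), `L`
#'   (measurements per subject), `feature_kinds` (list per feature; each a
#'   list with `kind` `"continuous"` or `"categorical"` and, when
#'   categorical, `levels`), and `outcome_kind` (`"real"` or a list
#'   `list(kind = "categorical", levels = ...)`).
#' @return A `vada_nets` object: a flat named list of weight matrices plus a
#'   `meta` attribute recording dimensions and kinds.
#' @export
build_networks <- function(arch, spec) {
  stopifnot(inherits(arch, "vada_arch"))
  D <- as.integer(spec$D); L <- as.integer(spec$L)
  fk <- spec$feature_kinds
  P <- length(fk)
  stopifnot(D >= 1L, L >= 1L, P >= 1L)
  con_idx <- which(vapply(fk, function(f) f$kind == "continuous", TRUE))
  cat_idx <- which(vapply(fk, function(f) f$kind == "categorical", TRUE))
  cat_G <- vapply(fk[cat_idx], function(f) length(f$levels), 1L)
  P_enc <- length(con_idx) + sum(cat_G)  # one-hot expanded input width

  ok <- spec$outcome_kind
  y_cat <- is.list(ok) && identical(ok$kind, "categorical")
  G_y <- if (y_cat) length(ok$levels) else 0L
  y_in <- if (y_cat) L * G_y else L

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(arch$seed)

  xe <- init_dense(P_enc, arch$hidden_x, list(m = D, v = D), arch$init)
  xd_heads <- list()
  if (length(con_idx)) { xd_heads$m <- length(con_idx); xd_heads$v <- length(con_idx) }
  if (length(cat_idx)) for (j in seq_along(cat_idx)) {
    xd_heads[[paste0("c", j)]] <- cat_G[j]
  }
  xd <- init_dense(D, arch$hidden_x, xd_heads, arch$init)
  ye <- init_dense(y_in, arch$hidden_y, list(m = L, v = L), arch$init)
  yd_heads <- if (y_cat) list(c = L * G_y) else list(m = L, v = L)
  yd <- init_dense(L, arch$hidden_y, yd_heads, arch$init)
  if (!y_cat && arch$init == "glorot" && arch$hidden_y >= L) {
    # Near-identity initialization of the outcome branch: the pure
    # outcomes start as (approximately) the standardized outcomes
    # themselves and the decoder passes them through, so the
    # reconstruction path is informative from the first step and training
    # only has to learn the cross-measurement coupling. With random
    # initialization the outcome branch either collapses (the decoder
    # explains y marginally and q(u|y) falls back to the prior) or settles
    # in a latent parameterization of u that the cluster-linear marginal
    # models cannot track.
    ye <- identity_y_init(ye, y_in, arch$hidden_y, L, enc = TRUE)
    yd <- identity_y_init(yd, L, arch$hidden_y, L, enc = FALSE)
  }

  w <- c(prefix_names(xe, "xe_"), prefix_names(xd, "xd_"),
         prefix_names(ye, "ye_"), prefix_names(yd, "yd_"))
  structure(w, class = "vada_nets",
            meta = list(arch = arch, D = D, L = L, P = P,
                        con_idx = con_idx, cat_idx = cat_idx, cat_G = cat_G,
                        P_enc = P_enc, outcome_kind = ok, y_cat = y_cat, G_y = G_y))
}

prefix_names <- function(lst, p) stats::setNames(lst, paste0(p, names(lst)))

# overwrite the first L hidden units with a scaled identity pathway:
# mean head output = 2 * tanh(0.5 * input[1:L]) ~= input[1:L]
identity_y_init <- function(w, n_in, n_hidden, L, enc) {
  w$W1[, seq_len(L)] <- 0
  w$W1[cbind(seq_len(L), seq_len(L))] <- 0.5
  w$W_m[] <- 0
  w$W_m[cbind(seq_len(L), seq_len(L))] <- 2
  w$W_v[] <- 0
  # confident encoder posterior, moderate decoder variance
  w$b_v[] <- if (enc) log(0.01) else log(0.25)
  w
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

net_meta <- function(nets) attr(nets, "meta")

act_fun <- function(name) {
  switch(name, tanh = tanh, relu = function(x) pmax(x, 0),
         stop("unknown activation ", name))
}

# numeric forward through one dense net; x is a matrix of row inputs,
# returns the named list of head outputs (linear, before any exp/softmax)
dense_forward <- function(w, prefix, x, activation) {
  if (!all(is.finite(x))) stop("non-finite input to network ", prefix)
  h <- act_fun(activation)(x %*% w[[paste0(prefix, "W1")]] +
                             matrix(w[[paste0(prefix, "b1")]],
                                    nrow(x), length(w[[paste0(prefix, "b1")]]),
                                    byrow = TRUE))
  if (!all(is.finite(h))) stop("non-finite activations in hidden layer of ", prefix)
  heads <- grep(paste0("^", prefix, "W_"), names(w), value = TRUE)
  out <- list()
  for (wh in heads) {
    hn <- sub(paste0(prefix, "W_"), "", wh)
    bh <- w[[paste0(prefix, "b_", hn)]]
    out[[hn]] <- h %*% w[[wh]] + matrix(bh, nrow(h), length(bh), byrow = TRUE)
  }
  out
}

softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# One-hot expansion of the feature matrix for encoder input. X is an
# (N*L) x P matrix; categorical columns hold 1-based integer codes.
expand_features <- function(X, meta) {
  if (length(meta$cat_idx) == 0L) {
    return(X[, meta$con_idx, drop = FALSE])
  }
  blocks <- list(X[, meta$con_idx, drop = FALSE])
  for (j in seq_along(meta$cat_idx)) {
    G <- meta$cat_G[j]
    v <- X[, meta$cat_idx[j]]
    oh <- matrix(0, nrow(X), G)
    oh[cbind(seq_len(nrow(X)), v)] <- 1
    blocks[[length(blocks) + 1L]] <- oh
  }
  do.call(cbind, blocks)
}

#' Apply the X-encoder
#'
#' @param nets A `vada_nets` bundle.
#' @param x A feature matrix with one row per observation (categorical
#'   features as integer codes; one-hot expansion happens internally), or a
#'   single feature vector.
#' @return A list with `mu` and `sigma2` matrices (rows = observations,
#'   columns = latent dimensions); variances are floored at `1e-6`.
#' @export
apply_x_encoder <- function(nets, x) {
  meta <- net_meta(nets)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  stopifnot(ncol(x) == meta$P)
  xe <- expand_features(x, meta)
  o <- dense_forward(nets, "xe_", xe, meta$arch$activation)
  list(mu = o$m, sigma2 = pmax(exp(o$v), VAR_FLOOR))
}

#' Apply the X-decoder
#'
#' @param nets A `vada_nets` bundle.
#' @param z Latent matrix (rows = observations) or single latent vector.
#' @return A list with `mu`/`sigma2` for the continuous features (columns in
#'   the order of the continuous feature indices) and `prob`, a list of
#'   simplex matrices, one per categorical feature.
#' @export
apply_x_decoder <- function(nets, z) {
  meta <- net_meta(nets)
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  stopifnot(ncol(z) == meta$D)
  o <- dense_forward(nets, "xd_", z, meta$arch$activation)
  out <- list()
  if (length(meta$con_idx)) {
    out$mu <- o$m
    out$sigma2 <- pmax(exp(o$v), VAR_FLOOR)
  }
  if (length(meta$cat_idx)) {
    out$prob <- lapply(seq_along(meta$cat_idx), function(j) softmax_rows(o[[paste0("c", j)]]))
  }
  out
}

y_enc_input <- function(y, meta) {
  if (!meta$y_cat) return(y)
  oh <- matrix(0, nrow(y), meta$L * meta$G_y)
  for (l in seq_len(meta$L)) {
    oh[cbind(seq_len(nrow(y)), (l - 1L) * meta$G_y + y[, l])] <- 1
  }
  oh
}

#' Apply the Y-encoder
#'
#' @param nets A `vada_nets` bundle.
#' @param y Outcome matrix (rows = subjects, `L` columns; categorical
#'   outcomes as integer codes) or a single length-`L` vector.
#' @return A list with `mu` and `sigma2` (rows = subjects, `L` columns).
#' @export
apply_y_encoder <- function(nets, y) {
  meta <- net_meta(nets)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  stopifnot(ncol(y) == meta$L)
  o <- dense_forward(nets, "ye_", y_enc_input(y, meta), meta$arch$activation)
  list(mu = o$m, sigma2 = pmax(exp(o$v), VAR_FLOOR))
}

#' Apply the Y-decoder
#'
#' Consumes the whole length-`L` pure-outcome vector of each subject jointly,
#' inducing within-subject dependence of the observed outcomes.
#'
#' @param nets A `vada_nets` bundle.
#' @param u Pure-outcome matrix (rows = subjects, `L` columns) or vector.
#' @return For real outcomes a list with `mu`, `sigma2` (rows = subjects);
#'   for categorical outcomes a list with `prob`, a list of `L` simplex
#'   matrices.
#' @export
apply_y_decoder <- function(nets, u) {
  meta <- net_meta(nets)
  if (!is.matrix(u)) u <- matrix(u, nrow = 1L)
  stopifnot(ncol(u) == meta$L)
  o <- dense_forward(nets, "yd_", u, meta$arch$activation)
  if (!meta$y_cat) {
    list(mu = o$m, sigma2 = pmax(exp(o$v), VAR_FLOOR))
  } else {
    G <- meta$G_y
    list(prob = lapply(seq_len(meta$L), function(l) {
      softmax_rows(o$c[, (l - 1L) * G + seq_len(G), drop = FALSE])
    }))
  }
}

n_parameters <- function(nets) sum(vapply(nets, length, 1L))
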