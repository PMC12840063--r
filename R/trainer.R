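#' Standardize a longitudinal dataset
#'
#' Rescales continuous features and real outcomes to zero mean and unit
#' variance. When `stats` is supplied (e.g. computed on a training split),
#' those constants are reused — the held-out contract: test data are
#' standardized with training statistics. Constant columns are centered
#' only. Categorical columns are untouched.
#'
#' @param data A [vada_data()] object.
#' @param stats Optional statistics from a previous call.
#' @return A list with `data` (standardized) and `stats` (means/sds plus an
#'   inverse transform for outcomes).
#' @export
standardize <- function(data, stats = NULL) {
  con <- which(vapply(data$feature_kinds, function(f) f$kind == "continuous", TRUE))
  y_real <- !is.list(data$outcome_kind)
  if (is.null(stats)) {
    xm <- if (length(con)) colMeans(data$X[, con, drop = FALSE]) else numeric(0)
    xs <- if (length(con)) apply(data$X[, con, drop = FALSE], 2L, stats::sd) else numeric(0)
    xs[!is.finite(xs) | xs < 1e-12] <- 1
    ym <- if (y_real) mean(data$y) else 0
    ys <- if (y_real) stats::sd(as.numeric(data$y)) else 1
    if (!is.finite(ys) || ys < 1e-12) ys <- 1
    stats <- list(x_mean = xm, x_sd = xs, y_mean = ym, y_sd = ys, con = con)
  }
  X <- data$X
  if (length(stats$con)) {
    X[, stats$con] <- sweep(sweep(X[, stats$con, drop = FALSE], 2L, stats$x_mean),
                            2L, stats$x_sd, "/")
  }
  y <- data$y
  if (y_real) y <- (y - stats$y_mean) / stats$y_sd
  out <- data
  out$X <- X; out$y <- y
  list(data = out, stats = stats)
}

#' Invert outcome standardization
#' @param y Standardized outcome values.
#' @param stats Statistics from [standardize()].
#' @return Values on the original outcome scale.
#' @export
unstandardize_y <- function(y, stats) y * stats$y_sd + stats$y_mean

#' Split a dataset into training and test sets by subject
#'
#' All `L` measurements of a subject stay together. The default ratio 0.8
#' is the 4/1 training/testing protocol.
#'
#' @param data A [vada_data()] object.
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list with `train` and `test` datasets.
#' @export
split_subjects <- function(data, ratio = 0.8, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1, data$N >= 2L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_train <- round(data$N * ratio)
  idx <- sample.int(data$N)
  list(train = subset_subjects(data, sort(idx[seq_len(n_train)])),
       test = subset_subjects(data, sort(idx[-seq_len(n_train)])))
}

subset_subjects <- function(data, idx) {
  rows <- as.numeric(outer(seq_len(data$L), (idx - 1L) * data$L, "+"))
  rows <- sort(rows)
  truth <- NULL
  if (!is.null(data$truth)) {
    truth <- list(c_true = data$truth$c_true[idx],
                  Z_true = data$truth$Z_true[rows, , drop = FALSE],
                  u_true = data$truth$u_true[idx, , drop = FALSE])
  }
  vada_data(data$subject_ids[idx], data$X[rows, , drop = FALSE],
            data$y[idx, , drop = FALSE], data$feature_kinds,
            data$outcome_kind, truth)
}

# --- Adam -------------------------------------------------------------------

adam_state <- function(theta) {
  list(m = lapply(theta, function(x) x * 0),
       v = lapply(theta, function(x) x * 0), t = 0L)
}

adam_step <- function(theta, grads, st, lr = 1e-3, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(theta)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    theta[[nm]] <- theta[[nm]] - lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(theta = theta, st = st)
}

# --- training ---------------------------------------------------------------

#' Fit the model by stochastic gradient variational Bayes
#'
#' Trains the four networks and the mixture/marginal-model parameters
#' jointly by Adam on the negative ELBO, using the reparameterization trick
#' with `M` Monte-Carlo samples per step (default 1). No pretraining is
#' used: mixture weights start uniform, component means standard-normal,
#' variances at 1, marginal effects near zero. Subjects are reshuffled
#' every epoch; the last partial batch is kept. Standardization statistics
#' are fitted on the supplied (training) data and stored for prediction.
#'
#' @param data A [vada_data()] object or a long-format data frame (see
#'   [as_vada_data()]; extra arguments are passed through).
#' @param D Latent dimension.
#' @param K Number of clusters.
#' @param epochs Training epochs (protocol default 500).
#' @param batch_subjects Subjects per minibatch (default 128).
#' @param lr Adam learning rate (default 0.001).
#' @param M Monte-Carlo samples per step (default 1).
#' @param seed Integer seed controlling initialization, shuffling and noise.
#' @param arch A [vada_arch()]; its seed is overridden by `seed`.
#' @param standardize_data Standardize before training (default TRUE).
#' @param verbose Print the objective every `verbose` epochs (0 = silent).
#' @param init_mu_sd,init_sigma2 Initial spread of the component means and
#'   initial component variances.
#' @param warmstart_epoch After this many burn-in epochs of joint training
#'   the mixture block (pi, mu, sigma2) is re-localized by a Gaussian
#'   mixture fitted to the current latent posterior means, and joint
#'   training continues; 0 disables. Without it the mixture frequently
#'   collapses onto fewer effective components even when the latent space
#'   separates the clusters (see the vignette). The networks are never
#'   pretrained.
#' @param ... Passed to [as_vada_data()] when `data` is a data frame.
#' @return A `vada_fit` object with elements `nets`, `params`, `stats`,
#'   `history` (per-epoch tibble of elbo, recon_y, recon_x, kl) and
#'   `config`.
#' @export
vada <- function(data, D, K, epochs = 500L, batch_subjects = 128L, lr = 1e-3,
                 M = 1L, seed = 1L, arch = vada_arch(),
                 standardize_data = TRUE, verbose = 0L,
                 init_mu_sd = 1, init_sigma2 = 1,
                 warmstart_epoch = 30L, ...) {
  if (is.data.frame(data)) data <- as_vada_data(data, ...)
  stopifnot(inherits(data, "vada_data"), D >= 1L, K >= 1L, epochs >= 0L,
            batch_subjects >= 1L, M >= 1L)
  stats <- NULL
  if (standardize_data) {
    sd_ <- standardize(data)
    data <- sd_$data; stats <- sd_$stats
  }
  arch$seed <- as.integer(seed)
  nets <- build_networks(arch, data_spec(data, D))
  meta <- net_meta(nets)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  un <- list(pi_logit = matrix(0, 1L, K),
             mu = matrix(stats::rnorm(K * D, 0, init_mu_sd), K, D),
             log_sigma2 = matrix(log(init_sigma2), K, D),
             beta0 = matrix(stats::rnorm(K, 0, 0.1), 1L, K),
             beta = matrix(stats::rnorm(K * D, 0, 0.1), K, D),
             log_sigma2_u = matrix(0, 1L, K))

  wn <- names(nets)
  theta <- c(stats::setNames(lapply(wn, function(n) nets[[n]]), wn), un)
  opt <- adam_state(theta)
  history <- vector("list", epochs)
  N <- data$N; L <- data$L
  diag_msg <- NULL
  # fused forward/backward applies in the all-continuous real-outcome
  # single-sample configuration; otherwise the generic tape is used
  use_fast <- !meta$y_cat && length(meta$cat_idx) == 0L && M == 1L

  for (ep in seq_len(epochs)) {
    # mixture warm start: after a short burn-in of joint training the
    # latent geometry is informative; re-localize the mixture block on it
    # (a Gaussian mixture fit to the current latent posterior means). The
    # networks themselves are never pretrained or reset.
    if (warmstart_epoch > 0L && ep == warmstart_epoch + 1L && K > 1L &&
        epochs > warmstart_epoch) {
      mu_z_all <- apply_x_encoder(set_weights(nets, theta), data$X)$mu
      # hierarchical initialization inside mclust is quadratic in rows;
      # a seeded subsample is ample for re-localizing the mixture
      sub <- if (nrow(mu_z_all) > 2000L) sort(sample.int(nrow(mu_z_all), 2000L)) else seq_len(nrow(mu_z_all))
      gm <- tryCatch(fit_gmm(mu_z_all[sub, , drop = FALSE], K), error = function(e) {
        warning("mixture warm start skipped: ", conditionMessage(e))
        NULL
      })
      if (!is.null(gm) && !any(is.na(gm$parameters$mean))) {
        theta$mu <- t(gm$parameters$mean)
        sig <- gm$parameters$variance$sigma  # D x D x K diagonal
        theta$log_sigma2 <- t(apply(sig, 3L, function(S) log(pmax(diag(S), VAR_FLOOR))))
        if (D == 1L) theta$log_sigma2 <- matrix(theta$log_sigma2, K, 1L)
        theta$pi_logit <- matrix(log(pmax(gm$parameters$pro, 1e-6)), 1L, K)
        # align the per-cluster marginal models with the new components,
        # otherwise the u-branch densities pull the responsibilities back
        # to the pre-restart configuration
        mu_u_all <- apply_y_encoder(set_weights(nets, theta), data$y)$mu
        u_vec <- as.numeric(t(mu_u_all))
        z_all <- gmm_probs(gm, mu_z_all)
        lab_ws <- merge_subject_clusters(z_all, rep(seq_len(N), each = L))
        lab_obs <- rep(lab_ws, each = L)
        for (k in seq_len(K)) {
          rows <- which(lab_obs == k)
          if (length(rows) > D + 2L) {
            cf <- stats::lm.fit(cbind(1, mu_z_all[rows, , drop = FALSE]), u_vec[rows])
            theta$beta0[1L, k] <- cf$coefficients[1L]
            bk <- cf$coefficients[-1L]; bk[is.na(bk)] <- 0
            theta$beta[k, ] <- bk
            theta$log_sigma2_u[1L, k] <- log(max(stats::var(cf$residuals), VAR_FLOOR))
          }
        }
        for (nm in c("mu", "log_sigma2", "pi_logit", "beta0", "beta",
                     "log_sigma2_u")) {
          opt$m[[nm]][] <- 0; opt$v[[nm]][] <- 0
        }
      }
    }
    ord <- sample.int(N)
    starts <- seq(1L, N, by = batch_subjects)
    comp <- c(elbo = 0, recon_y = 0, recon_x = 0, kl = 0)
    for (s in starts) {
      idx <- sort(ord[s:min(s + batch_subjects - 1L, N)])
      B <- length(idx)
      rows <- rep((idx - 1L) * L, each = L) + seq_len(L)
      eps <- lapply(seq_len(M), function(m) {
        list(z = matrix(stats::rnorm(B * L * D), B * L, D),
             u = matrix(stats::rnorm(B * L), B, L))
      })
      if (use_fast) {
        fb <- elbo_grad_fast(theta, data$X[rows, , drop = FALSE],
                             data$y[idx, , drop = FALSE],
                             eps[[1L]]$z, eps[[1L]]$u,
                             list(B = B, L = L, D = D, P = data$P, K = K))
        if (!is.finite(fb$elbo)) {
          diag_msg <- sprintf("non-finite objective at epoch %d; training aborted, returning last finite state", ep)
          warning(diag_msg)
          break
        }
        grads <- lapply(fb$grads, function(x) -x)  # minimizing -elbo
        vals <- c(fb$elbo, fb$recon_y, fb$recon_x, fb$kl)
      } else {
        batch <- subset_subjects(data, idx)
        tp <- ad_tape()
        wnodes <- stats::setNames(lapply(wn, function(n) ad_param(tp, theta[[n]])), wn)
        unodes <- lapply(theta[c("pi_logit", "mu", "log_sigma2", "beta0", "beta",
                                 "log_sigma2_u")], function(x) ad_param(tp, x))
        ob <- elbo_tape(tp, wnodes, unodes, batch, eps, meta)
        loss <- ad_scale(tp, ob$elbo, -1)
        if (!is.finite(loss$value[1L])) {
          diag_msg <- sprintf("non-finite objective at epoch %d; training aborted, returning last finite state", ep)
          warning(diag_msg)
          break
        }
        ad_backward(tp, loss)
        grads <- c(lapply(wnodes, function(nd) nd$grad),
                   lapply(unodes, function(nd) nd$grad))
        vals <- c(ob$elbo$value, ob$recon_y$value, ob$recon_x$value, ob$kl$value)
      }
      upd <- adam_step(theta, grads, opt, lr = lr)
      theta <- upd$theta; opt <- upd$st
      comp <- comp + (B / N) * vals
    }
    if (!is.null(diag_msg)) break
    history[[ep]] <- tibble::tibble(epoch = ep, elbo = comp[[1]],
                                    recon_y = comp[[2]], recon_x = comp[[3]],
                                    kl = comp[[4]])
    if (verbose > 0L && ep %% verbose == 0L) {
      pl <- as.numeric(theta$pi_logit); pv <- exp(pl - max(pl)); pv <- pv / sum(pv)
      message(sprintf("epoch %4d  elbo %10.4f  kl %8.4f  pi %s", ep, comp[[1]],
                      comp[[4]], paste(round(pv, 2), collapse = "/")))
    }
  }

  for (n in wn) nets[[n]] <- theta[[n]]
  params <- uncon_to_params(theta[c("pi_logit", "mu", "log_sigma2", "beta0",
                                    "beta", "log_sigma2_u")])
  structure(list(nets = nets, params = params, stats = stats,
                 history = dplyr::bind_rows(history),
                 config = list(D = D, K = K, epochs = epochs,
                               batch_subjects = batch_subjects, lr = lr, M = M,
                               seed = seed, arch = arch,
                               standardized = standardize_data),
                 diagnostic = diag_msg),
            class = "vada_fit")
}

#' @export
print.vada_fit <- function(x, ...) {
  cat("<vada_fit> D=", x$config$D, " K=", x$config$K,
      "; trained ", nrow(x$history), " epochs", sep = "")
  if (nrow(x$history)) cat(sprintf("; final elbo %.4f", utils::tail(x$history$elbo, 1L)))
  cat("\n")
  invisible(x)
}

set_weights <- function(nets, theta) {
  for (n in names(nets)) if (!is.null(theta[[n]])) nets[[n]] <- theta[[n]]
  nets
}

# standardize new data with a fit's stored stats
apply_fit_stats <- function(fit, data) {
  if (is.null(fit$stats)) data else standardize(data, fit$stats)$data
}
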