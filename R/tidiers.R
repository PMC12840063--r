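#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the mixture and marginal-model parameters of a fit
#'
#' @param x A `vada_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per cluster: weight `pi`, intercept
#'   `beta0`, residual variance `sigma2_u`, and the norms of the component
#'   mean and marginal-effect vectors.
#' @method tidy vada_fit
#' @export
tidy.vada_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(cluster = seq_len(p$K), pi = p$pi, beta0 = p$beta0,
                 sigma2_u = p$sigma2_u,
                 mu_norm = sqrt(rowSums(p$mu^2)),
                 beta_norm = sqrt(rowSums(p$beta^2)))
}

#' One-row summary of a fit
#'
#' @param x A `vada_fit` object.
#' @param ... Unused.
#' @return A tibble with dimensions, epochs and the final objective value.
#' @method glance vada_fit
#' @export
glance.vada_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(D = x$config$D, K = x$config$K, epochs = nrow(h),
                 elbo = if (nrow(h)) h$elbo[nrow(h)] else NA_real_,
                 recon_y = if (nrow(h)) h$recon_y[nrow(h)] else NA_real_,
                 recon_x = if (nrow(h)) h$recon_x[nrow(h)] else NA_real_,
                 kl = if (nrow(h)) h$kl[nrow(h)] else NA_real_)
}

#' Training-history plot
#'
#' @param object A `vada_fit` object.
#' @param ... Unused.
#' @return A ggplot of the objective components per epoch.
#' @method autoplot vada_fit
#' @export
autoplot.vada_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "component", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training objective components")
}

#' Benchmark metrics plot
#'
#' @param object A `vada_metrics` tibble from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot of per-replicate metric values by method and scenario.
#' @method autoplot vada_metrics
#' @export
autoplot.vada_metrics <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_grid(metric ~ scenario, scales = "free_y") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Latent-representation plot
#'
#' Scatter of the first two latent coordinates of the posterior-mean
#' representations, colored by cluster label.
#'
#' @param fit A `vada_fit` object.
#' @param data A [vada_data()] object.
#' @param M,seed Passed to [cluster_x()].
#' @return A ggplot.
#' @export
plot_latent <- function(fit, data, M = 100L, seed = 1L) {
  Z <- encode_features(fit, data)
  cl <- cluster_x(fit, data, M = M, seed = seed)
  df <- tibble::tibble(z1 = Z[, 1L], z2 = Z[, min(2L, ncol(Z))],
                       cluster = factor(rep(cl$labels, each = data$L)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z1, y = .data$z2,
                                   color = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "latent dim 1", y = "latent dim 2")
}
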