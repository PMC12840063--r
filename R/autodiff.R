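# Minimal tape-based reverse-mode automatic differentiation over dense
# matrices. Only the operations needed by the variational objective are
# implemented. Nodes are environments holding a value, an accumulated
# gradient and a backward closure; the tape records creation order so the
# backward sweep is a single reverse iteration (the graph is built in
# topological order by construction).
#
# Broadcasting: binary elementwise ops accept operands of equal shape, or a
# second operand that is 1x1, a 1xC row or an Rx1 column; gradients are
# reduced (sum / colSums / rowSums) back to the operand's shape.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = NULL, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ad_const <- function(tape, x) ad_node(tape, as_mat(x))

ad_param <- function(tape, x) ad_node(tape, as_mat(x))

ad_value <- function(nd) nd$value

#' @noRd
ad_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
}

# Run the backward sweep from `loss` (must be 1x1). Gradients of every node
# reachable from the loss are left in node$grad.
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad)
    for (j in seq_along(gs)) {
      if (!is.null(gs[[j]])) ad_accum(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(loss)
}

# --- shape helpers -----------------------------------------------------------

bcast_expand <- function(v, R, C) {
  dv <- dim(v)
  if (dv[1] == R && dv[2] == C) return(v)
  if (dv[1] == 1L && dv[2] == 1L) return(matrix(v[1L], R, C))
  if (dv[1] == 1L && dv[2] == C) return(matrix(v, R, C, byrow = TRUE))
  if (dv[1] == R && dv[2] == 1L) return(matrix(v, R, C))
  stop("non-conformable broadcast: ", dv[1], "x", dv[2], " vs ", R, "x", C)
}

bcast_reduce <- function(g, dv) {
  R <- nrow(g); C <- ncol(g)
  if (dv[1] == R && dv[2] == C) return(g)
  if (dv[1] == 1L && dv[2] == 1L) return(matrix(sum(g), 1L, 1L))
  if (dv[1] == 1L && dv[2] == C) return(matrix(colSums(g), 1L, C))
  if (dv[1] == R && dv[2] == 1L) return(matrix(rowSums(g), R, 1L))
  stop("bad reduce")
}

# --- operations --------------------------------------------------------------

ad_mm <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(g) {
    list(tcrossprod(g, b$value), crossprod(a$value, g))
  })
}

ad_t <- function(tape, a) {
  ad_node(tape, t(a$value), list(a), function(g) list(t(g)))
}

ad_add <- function(tape, a, b) {
  R <- nrow(a$value); C <- ncol(a$value)
  ad_node(tape, a$value + bcast_expand(b$value, R, C), list(a, b), function(g) {
    list(g, bcast_reduce(g, dim(b$value)))
  })
}

ad_sub <- function(tape, a, b) {
  R <- nrow(a$value); C <- ncol(a$value)
  ad_node(tape, a$value - bcast_expand(b$value, R, C), list(a, b), function(g) {
    list(g, -bcast_reduce(g, dim(b$value)))
  })
}

ad_mul <- function(tape, a, b) {
  R <- nrow(a$value); C <- ncol(a$value)
  be <- bcast_expand(b$value, R, C)
  ad_node(tape, a$value * be, list(a, b), function(g) {
    list(g * be, bcast_reduce(g * a$value, dim(b$value)))
  })
}

ad_div <- function(tape, a, b) {
  R <- nrow(a$value); C <- ncol(a$value)
  be <- bcast_expand(b$value, R, C)
  v <- a$value / be
  ad_node(tape, v, list(a, b), function(g) {
    list(g / be, bcast_reduce(-g * v / be, dim(b$value)))
  })
}

ad_neg <- function(tape, a) {
  ad_node(tape, -a$value, list(a), function(g) list(-g))
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, list(a), function(g) list(g * s))
}

ad_addc <- function(tape, a, cmat) {
  ad_node(tape, a$value + cmat, list(a), function(g) list(g))
}

ad_exp <- function(tape, a) {
  v <- exp(a$value)
  ad_node(tape, v, list(a), function(g) list(g * v))
}

ad_log <- function(tape, a) {
  ad_node(tape, log(a$value), list(a), function(g) list(g / a$value))
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$value)
  ad_node(tape, v, list(a), function(g) list(g * (1 - v * v)))
}

ad_sqr <- function(tape, a) {
  ad_node(tape, a$value * a$value, list(a), function(g) list(2 * g * a$value))
}

# clamp below at constant c; subgradient 0 on the clamped region
ad_clamp_min <- function(tape, a, c) {
  act <- a$value > c
  ad_node(tape, pmax(a$value, c), list(a), function(g) list(g * act))
}

ad_sum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    list(matrix(g[1L], nrow(a$value), ncol(a$value)))
  })
}

ad_rowsum <- function(tape, a) {
  ad_node(tape, matrix(rowSums(a$value), ncol = 1L), list(a), function(g) {
    list(matrix(g, nrow(a$value), ncol(a$value)))
  })
}

ad_colsum <- function(tape, a) {
  ad_node(tape, matrix(colSums(a$value), nrow = 1L), list(a), function(g) {
    list(matrix(g, nrow(a$value), ncol(a$value), byrow = TRUE))
  })
}

ad_cbind <- function(tape, lst) {
  cols <- vapply(lst, function(x) ncol(x$value), 1L)
  ends <- cumsum(cols)
  starts <- ends - cols + 1L
  ad_node(tape, do.call(cbind, lapply(lst, ad_value)), lst, function(g) {
    lapply(seq_along(lst), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ad_getrow <- function(tape, a, i) {
  ad_node(tape, a$value[i, , drop = FALSE], list(a), function(g) {
    z <- matrix(0, nrow(a$value), ncol(a$value))
    z[i, ] <- g
    list(z)
  })
}

# Bijective reshuffle: out value is matrix(a$value[idx], R, C); idx must be a
# permutation of seq_along(a$value). Used to move between subject-major
# (N x L) layouts and stacked observation ((N*L) x 1) layouts.
ad_permute <- function(tape, a, idx, R, C) {
  ad_node(tape, matrix(a$value[idx], R, C), list(a), function(g) {
    gp <- numeric(length(a$value))
    gp[idx] <- g
    list(matrix(gp, nrow(a$value), ncol(a$value)))
  })
}

# log-sum-exp over rows (returns Rx1); max-subtraction for stability. The
# subtracted rowwise max is treated as a constant, which yields the exact
# softmax gradient.
ad_lse_rows <- function(tape, a) {
  m <- matrix(apply(a$value, 1L, max), ncol = 1L)
  e <- ad_exp(tape, ad_node(tape, a$value - matrix(m, nrow(a$value), ncol(a$value)),
                            list(a), function(g) list(g)))
  ad_addc(tape, ad_log(tape, ad_rowsum(tape, e)), m)
}

# rowwise softmax built from lse
ad_softmax_rows <- function(tape, a) {
  lse <- ad_lse_rows(tape, a)
  ad_exp(tape, ad_sub(tape, a, lse))
}

# --- fused operations for the training hot path ------------------------------

# dense layer with activation: act(x W + b); x may be a node or a constant
# matrix. One node instead of four, with analytic gradients.
ad_dense_layer <- function(tape, x, W, b, activation = c("tanh", "relu", "linear")) {
  activation <- match.arg(activation)
  x_is_node <- is.environment(x)
  xv <- if (x_is_node) x$value else x
  pre <- xv %*% W$value
  pre <- pre + matrix(b$value, nrow(pre), ncol(pre), byrow = TRUE)
  v <- switch(activation, tanh = tanh(pre), relu = pmax(pre, 0), linear = pre)
  parents <- if (x_is_node) list(x, W, b) else list(W, b)
  ad_node(tape, v, parents, function(g) {
    gp <- switch(activation,
                 tanh = g * (1 - v * v),
                 relu = g * (pre > 0),
                 linear = g)
    gW <- crossprod(xv, gp)
    gb <- matrix(colSums(gp), 1L)
    if (x_is_node) list(tcrossprod(gp, W$value), gW, gb) else list(gW, gb)
  })
}

# summed Gaussian log-density of constant data x under mean node mu and
# log-variance node lv (floored at LOGV_FLOOR): one scalar node.
ad_gauss_recon <- function(tape, x, mu, lv) {
  lvv <- pmax(lv$value, LOGV_FLOOR)
  act <- lv$value > LOGV_FLOOR
  d <- x - mu$value
  e <- exp(-lvv)
  q <- d * d * e
  val <- -0.5 * sum(log(2 * pi) + lvv + q)
  ad_node(tape, matrix(val, 1L, 1L), list(mu, lv), function(g) {
    gs <- g[1L]
    list(gs * d * e, gs * (-0.5) * (1 - q) * act)
  })
}

# reparameterized draw mu + exp(lv/2) * eps with constant noise eps;
# lv floored at LOGV_FLOOR
ad_reparam <- function(tape, mu, lv, eps) {
  lvv <- pmax(lv$value, LOGV_FLOOR)
  act <- lv$value > LOGV_FLOOR
  sd <- exp(0.5 * lvv)
  ad_node(tape, mu$value + sd * eps, list(mu, lv), function(g) {
    list(g, g * 0.5 * sd * eps * act)
  })
}
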