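# Hand-fused forward/backward pass for the training objective in the
# dominant configuration: all features continuous, real outcome, one
# Monte-Carlo sample. Mathematically identical to the tape path
# (elbo_tape); equality of value and of every gradient is asserted in the
# test suite. The trainer dispatches here when the configuration allows.

elbo_grad_fast <- function(theta, X, Y, eps_z, eps_u, dims) {
  B <- dims$B; L <- dims$L; D <- dims$D; P <- dims$P; K <- dims$K
  R <- B * L
  grp <- rep(seq_len(B), each = L)
  F0 <- LOGV_FLOOR
  # subject-major stacking of B x L matrices into (B*L) x 1 columns
  stk <- function(m) as.numeric(t(m))

  # ---- forward -------------------------------------------------------------
  He_pre <- X %*% theta$xe_W1
  He_pre <- He_pre + rep(theta$xe_b1, each = R)
  He <- tanh(He_pre)
  Mz <- He %*% theta$xe_W_m + rep(theta$xe_b_m, each = R)
  Vz_raw <- He %*% theta$xe_W_v + rep(theta$xe_b_v, each = R)
  actz <- Vz_raw > F0
  Vz <- pmax(Vz_raw, F0)
  Sz <- exp(0.5 * Vz)
  Z <- Mz + Sz * eps_z

  Hd_pre <- Z %*% theta$xd_W1
  Hd_pre <- Hd_pre + rep(theta$xd_b1, each = R)
  Hd <- tanh(Hd_pre)
  Mx <- Hd %*% theta$xd_W_m + rep(theta$xd_b_m, each = R)
  Vx_raw <- Hd %*% theta$xd_W_v + rep(theta$xd_b_v, each = R)
  actx <- Vx_raw > F0
  Vx <- pmax(Vx_raw, F0)
  Dx <- X - Mx
  Ex <- exp(-Vx)
  Qx <- Dx * Dx * Ex
  recon_x <- -0.5 * sum(LOG2PI + Vx + Qx) / B

  Hy_pre <- Y %*% theta$ye_W1
  Hy_pre <- Hy_pre + rep(theta$ye_b1, each = B)
  Hy <- tanh(Hy_pre)
  Mu <- Hy %*% theta$ye_W_m + rep(theta$ye_b_m, each = B)
  Vu_raw <- Hy %*% theta$ye_W_v + rep(theta$ye_b_v, each = B)
  actu <- Vu_raw > F0
  Vu <- pmax(Vu_raw, F0)
  Su <- exp(0.5 * Vu)
  U <- Mu + Su * eps_u

  Hyd_pre <- U %*% theta$yd_W1
  Hyd_pre <- Hyd_pre + rep(theta$yd_b1, each = B)
  Hyd <- tanh(Hyd_pre)
  My <- Hyd %*% theta$yd_W_m + rep(theta$yd_b_m, each = B)
  Vy_raw <- Hyd %*% theta$yd_W_v + rep(theta$yd_b_v, each = B)
  acty <- Vy_raw > F0
  Vy <- pmax(Vy_raw, F0)
  Dy <- Y - My
  Ey <- exp(-Vy)
  Qy <- Dy * Dy * Ey
  recon_y <- -0.5 * sum(LOG2PI + Vy + Qy) / B

  # mixture quantities
  lp <- as.numeric(theta$pi_logit)
  log_pi <- lp - (max(lp) + log(sum(exp(lp - max(lp)))))     # length K
  IU <- exp(-pmax(as.numeric(theta$log_sigma2_u), F0))       # length K
  lvu <- pmax(as.numeric(theta$log_sigma2_u), F0)
  act_lvu <- as.numeric(theta$log_sigma2_u) > F0
  lvz_raw <- theta$log_sigma2                                 # K x D
  act_lvz <- lvz_raw > F0
  lvz <- pmax(lvz_raw, F0)
  IZ <- exp(-lvz)                                             # K x D
  MI <- theta$mu * IZ                                         # K x D
  cz <- rowSums(theta$mu^2 * IZ + lvz)                        # length K

  # responsibilities of the single sample
  U_bl <- stk(U)
  MUk <- Z %*% t(theta$beta) + rep(as.numeric(theta$beta0), each = R)  # R x K
  DU <- U_bl - MUk
  ld_u <- -0.5 * (LOG2PI + rep(lvu, each = R) + DU * DU * rep(IU, each = R))
  Z2 <- Z * Z
  A1 <- Z2 %*% t(IZ)
  A2 <- Z %*% t(MI)
  quad <- A1 - 2 * A2 + rep(cz, each = R)
  ld_z <- -0.5 * (D * LOG2PI + quad)
  S <- rowsum(ld_u + ld_z, grp, reorder = FALSE)              # B x K
  dimnames(S) <- NULL
  log_h <- S + rep(log_pi, each = B)
  mx <- do.call(pmax, c(as.data.frame(log_h), list(rep(-Inf, B))))
  wexp <- exp(log_h - mx)
  sw <- rowSums(wexp)
  H <- wexp / sw                                              # pi_tilde, B x K
  logH <- log_h - (mx + log(sw))

  # analytic KL with the variational means/variances
  S2z <- exp(Vz)
  Mu_bl <- stk(Mu)
  S2u_bl <- stk(exp(Vu))
  MUm <- Mz %*% t(theta$beta) + rep(as.numeric(theta$beta0), each = R)
  DM <- MUm - Mu_bl
  b2 <- theta$beta^2                                          # K x D
  qu <- DM * DM + S2u_bl + S2z %*% t(b2)
  a_u <- qu * rep(IU, each = R) + rep(lvu, each = R)
  Mz2S <- Mz * Mz + S2z
  a_z <- Mz2S %*% t(IZ) - 2 * (Mz %*% t(MI)) + rep(cz, each = R)
  A <- rowsum(a_u + a_z, grp, reorder = FALSE)                # B x K
  dimnames(A) <- NULL
  kl_mix <- 0.5 * rowSums(H * A)
  cross <- rowSums(H * rep(log_pi, each = B))
  ent <- rowSums(H * logH)
  ent_u <- 0.5 * rowSums(Vu)
  ent_z_subj <- 0.5 * rowsum(rowSums(Vz), grp, reorder = FALSE)
  kl <- sum(kl_mix - cross + ent - ent_u - ent_z_subj) / B
  elbo <- recon_y + recon_x - kl

  # ---- backward (gradient of elbo) -----------------------------------------
  g <- list()
  iB <- 1 / B

  # recon_y chain
  gMy <- Dy * Ey * iB
  gVy <- -0.5 * (1 - Qy) * acty * iB
  g$yd_W_m <- crossprod(Hyd, gMy); g$yd_b_m <- matrix(colSums(gMy), 1L)
  g$yd_W_v <- crossprod(Hyd, gVy); g$yd_b_v <- matrix(colSums(gVy), 1L)
  gHyd <- tcrossprod(gMy, theta$yd_W_m) + tcrossprod(gVy, theta$yd_W_v)
  gPy <- gHyd * (1 - Hyd * Hyd)
  g$yd_W1 <- crossprod(U, gPy); g$yd_b1 <- matrix(colSums(gPy), 1L)
  gU <- tcrossprod(gPy, theta$yd_W1)                          # B x L

  # recon_x chain
  gMx <- Dx * Ex * iB
  gVx <- -0.5 * (1 - Qx) * actx * iB
  g$xd_W_m <- crossprod(Hd, gMx); g$xd_b_m <- matrix(colSums(gMx), 1L)
  g$xd_W_v <- crossprod(Hd, gVx); g$xd_b_v <- matrix(colSums(gVx), 1L)
  gHd <- tcrossprod(gMx, theta$xd_W_m) + tcrossprod(gVx, theta$xd_W_v)
  gPd <- gHd * (1 - Hd * Hd)
  g$xd_W1 <- crossprod(Z, gPd); g$xd_b1 <- matrix(colSums(gPd), 1L)
  gZ <- tcrossprod(gPd, theta$xd_W1)                          # R x D

  # KL responsibilities chain: elbo contribution -kl_subj/B
  # dT/dH_k per subject (T = elbo part depending on H):
  gH <- (-0.5 * A + rep(log_pi, each = B) - logH - 1) * iB    # B x K
  # softmax backward onto log_h
  gS_ <- H * (gH - rowSums(gH * H))                           # B x K
  # log_pi receives: softmax path (rows of gS_), plus direct +H/B from cross
  g_log_pi <- colSums(gS_) + colSums(H) * iB
  # softmax of pi_logit backward
  pi_v <- exp(log_pi)
  g$pi_logit <- matrix(g_log_pi - sum(g_log_pi) * pi_v, 1L)

  g_ld <- gS_[grp, , drop = FALSE]                            # R x K
  # ld_u backward
  gDU <- -rep(IU, each = R) * DU * g_ld
  gU_bl <- rowSums(gDU)
  gMUk <- -gDU
  g_lvu_resp <- colSums(g_ld) * (-0.5) -
    colSums(g_ld * (-0.5) * DU * DU * rep(IU, each = R))      # d/dlvu of -0.5(lvu + DU^2 e^-lvu)
  # note: second term: -0.5 * DU^2 * d(e^-lvu)/dlvu = +0.5 DU^2 IU
  gZ <- gZ + gMUk %*% theta$beta
  g_beta <- crossprod(gMUk, Z)                                # K x D
  g_beta0 <- colSums(gMUk)
  # ld_z backward
  gq <- -0.5 * g_ld                                           # R x K (for A1 - 2A2 + cz)
  gZ <- gZ + 2 * Z * (gq %*% IZ) - 2 * (gq %*% MI)
  gIZ <- crossprod(gq, Z2)                                    # K x D
  gMI <- crossprod(-2 * gq, Z)                                # K x D
  g_cz <- colSums(gq)                                         # length K

  # KL analytic part: gA = -0.5 H / B on A, routed to a_u + a_z rows
  gA_rows <- (-0.5 * H * iB)[grp, , drop = FALSE]             # R x K
  # a_u backward
  gqu <- gA_rows * rep(IU, each = R)
  g_lvu_kl <- colSums(gA_rows) - colSums(gA_rows * qu * rep(IU, each = R))
  # (d a_u/d lvu = 1 - qu e^-lvu)
  gDM <- 2 * DM * gqu
  gMu_bl <- -rowSums(gDM)
  gS2u_bl <- rowSums(gqu)
  gS2z <- gqu %*% b2                                          # R x D
  g_b2 <- crossprod(gqu, S2z)                                 # K x D
  gMz <- gDM %*% theta$beta
  g_beta <- g_beta + crossprod(gDM, Mz) + 2 * theta$beta * g_b2
  g_beta0 <- g_beta0 + colSums(gDM)
  # a_z backward
  gMz <- gMz + 2 * Mz * (gA_rows %*% IZ) - 2 * (gA_rows %*% MI)
  gS2z <- gS2z + gA_rows %*% IZ
  gIZ <- gIZ + crossprod(gA_rows, Mz2S)
  gMI <- gMI + crossprod(-2 * gA_rows, Mz)
  g_cz <- g_cz + colSums(gA_rows)

  # cz = rowSums(mu^2 IZ + lvz)
  g_mu <- g_cz * (2 * theta$mu * IZ)
  gIZ <- gIZ + g_cz * theta$mu^2
  g_lvz <- matrix(g_cz, K, D)
  # MI = mu * IZ
  g_mu <- g_mu + gMI * IZ
  gIZ <- gIZ + gMI * theta$mu
  # IZ = exp(-lvz)
  g_lvz <- (g_lvz - gIZ * IZ) * act_lvz
  g$mu <- g_mu
  g$log_sigma2 <- g_lvz
  # lvu: responsibilities + analytic part; IU = exp(-lvu) handled above
  g$log_sigma2_u <- matrix((g_lvu_resp + g_lvu_kl) * act_lvu, 1L)
  g$beta <- g_beta
  g$beta0 <- matrix(g_beta0, 1L)

  # entropy-of-q terms: +0.5 sum(Vu)/B and +0.5 sum(Vz)/B in elbo
  gVu_direct <- matrix(0.5 * iB, B, L)
  gVz_direct <- matrix(0.5 * iB, R, D)

  # U appears in: recon path (gU), U_bl (responsibilities)
  gU <- gU + matrix(gU_bl, B, L, byrow = TRUE)
  # Mu appears in U and Mu_bl (KL)
  gMu <- gU + matrix(gMu_bl, B, L, byrow = TRUE)
  # Vu: via Su in U, via S2u_bl = exp(Vu), via entropy
  gVu <- (gU * 0.5 * Su * eps_u +
            matrix(gS2u_bl, B, L, byrow = TRUE) * exp(Vu) +
            gVu_direct) * actu
  g$ye_W_m <- crossprod(Hy, gMu); g$ye_b_m <- matrix(colSums(gMu), 1L)
  g$ye_W_v <- crossprod(Hy, gVu); g$ye_b_v <- matrix(colSums(gVu), 1L)
  gHy <- tcrossprod(gMu, theta$ye_W_m) + tcrossprod(gVu, theta$ye_W_v)
  gPe_y <- gHy * (1 - Hy * Hy)
  g$ye_W1 <- crossprod(Y, gPe_y); g$ye_b1 <- matrix(colSums(gPe_y), 1L)

  # Z chain: gZ accumulated from x-decoder, responsibilities
  # Mz appears in Z and in the KL (MUm, a_z, Mz2S)
  gMz_total <- gZ + gMz
  # Vz: via Sz in Z, via S2z = exp(Vz), via entropy
  gVz <- (gZ * 0.5 * Sz * eps_z + gS2z * S2z + gVz_direct) * actz
  g$xe_W_m <- crossprod(He, gMz_total); g$xe_b_m <- matrix(colSums(gMz_total), 1L)
  g$xe_W_v <- crossprod(He, gVz); g$xe_b_v <- matrix(colSums(gVz), 1L)
  gHe <- tcrossprod(gMz_total, theta$xe_W_m) + tcrossprod(gVz, theta$xe_W_v)
  gPe <- gHe * (1 - He * He)
  g$xe_W1 <- crossprod(X, gPe); g$xe_b1 <- matrix(colSums(gPe), 1L)

  list(elbo = elbo, recon_y = recon_y, recon_x = recon_x, kl = kl,
       pi_tilde = H, grads = g)
}
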