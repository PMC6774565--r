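## Latent linear dynamics: identify A, B, C, G by (ridge) least squares on
## latent-space training data, couple cells into the ECM through the
## analytically known mapping matrices (never regressed), and run the
## reduced-order multi-cell simulation by superposition: each cell evolves
## dz_c/dt = A z_c + B u + C z_e locally and contributes to the shared ECM
## state dz_e/dt = G z_e + sum_k (FA injection of cell k).

#' Assemble latent-space training data from full nonlinear runs
#'
#' Projects augmented trajectories onto the basis, estimates latent time
#' derivatives by forward differences at the sampling interval (the exact
#' adjoint of the explicit-Euler latent integrator), and evaluates the
#' analytically known focal-adhesion injection term of the ECM equation from
#' the recorded bond tables and the reconstructed cell FA forces.
#'
#' Sampling intervals during which the bond set changes carry a
#' discontinuous structural event (the attach/detach itself, which the model
#' handles through the re-assembled mapping matrices, not through A or G);
#' their derivative samples are spikes of order jump/dt and are excluded
#' from the regressions by default.
#'
#' @param trajs list of `ecm_trajectory` training runs.
#' @param basis a `latent_basis`.
#' @param drop_switch_frames exclude samples whose forward-difference
#'   interval spans a bond attach/detach event (default TRUE).
#' @return list with pooled matrices `zc`, `u`, `ze`, `dzc`, `dze`,
#'   `fa_inj` (rows aligned across all of them) and metadata.
#' @export
latent_training_data <- function(trajs, basis, drop_switch_frames = TRUE) {
  Vxe <- basis_block(basis, "Vxe", "proj")
  VFFAc <- basis_block(basis, "VFFAc", "rec")
  mu_ffa <- split_augmented(matrix(basis$mean_c, 1), "cell")$Ffa[1, ]
  zc_l <- list(); u_l <- list(); ze_l <- list()
  dzc_l <- list(); dze_l <- list(); inj_l <- list()
  for (traj in trajs) {
    dt <- diff(traj$times[1:2])
    aug <- build_augmented(traj)
    ze <- project_latent(aug$zeta_e, basis, "ecm")
    Tn <- nrow(ze)
    D_e <- traj$net$D_e
    keep <- rep(TRUE, Tn - 1L)
    if (drop_switch_frames && !is.null(traj$bonds)) {
      keep <- !vapply(seq_len(Tn - 1L), function(t)
        !identical(traj$bonds[[t]], traj$bonds[[t + 1L]]), TRUE)
      if (!any(keep)) keep <- rep(TRUE, Tn - 1L)
    }
    for (k in seq_along(traj$cells)) {
      zc <- project_latent(aug$zeta_c[[k]], basis, "cell")
      zc_l[[length(zc_l) + 1L]] <- zc[-Tn, , drop = FALSE][keep, , drop = FALSE]
      dzc_l[[length(dzc_l) + 1L]] <- (diff(zc) / dt)[keep, , drop = FALSE]
      u_l[[length(u_l) + 1L]] <- traj$u[[k]][-Tn, , drop = FALSE][keep, , drop = FALSE]
      ze_l[[length(ze_l) + 1L]] <- ze[-Tn, , drop = FALSE][keep, , drop = FALSE]
    }
    ## ECM equation samples: one set per run (cells pooled inside injection)
    dze_l[[length(dze_l) + 1L]] <- (diff(ze) / dt)[keep, , drop = FALSE]
    fhat_mats <- lapply(seq_along(traj$cells), function(k) {
      zck <- project_latent(aug$zeta_c[[k]], basis, "cell")
      sweep(tcrossprod(zck, VFFAc), 2, mu_ffa, "+")
    })
    ## the bond set is piecewise-constant in time: evaluate the injection
    ## block-wise with one matrix product per constant-bond segment
    switch_at <- c(TRUE, vapply(seq_len(Tn - 2L) + 1L, function(t)
      !identical(traj$bonds[[t]], traj$bonds[[t - 1L]]), TRUE))
    block_id <- cumsum(switch_at)
    inj <- matrix(0, Tn - 1L, basis$m_e)
    for (bid in unique(block_id)) {
      tt <- which(block_id == bid)
      bonds_t <- traj$bonds[[tt[1]]]
      for (k in seq_along(bonds_t)) {
        bb <- bonds_t[[k]]
        if (!nrow(bb)) next
        cols <- as.vector(t(outer(3 * (bb$i - 1L), 1:3, "+")))
        rows <- as.vector(t(outer(3 * (bb$j - 1L), 1:3, "+")))
        inj[tt, ] <- inj[tt, , drop = FALSE] -
          fhat_mats[[k]][tt, cols, drop = FALSE] %*%
          Vxe[rows, , drop = FALSE] / D_e
      }
    }
    inj_l[[length(inj_l) + 1L]] <- inj[keep, , drop = FALSE]
  }
  list(zc = do.call(rbind, zc_l), u = do.call(rbind, u_l),
       ze = do.call(rbind, ze_l), dzc = do.call(rbind, dzc_l),
       dze = do.call(rbind, dze_l), fa_inj = do.call(rbind, inj_l),
       m_c = basis$m_c, m_e = basis$m_e,
       D_c = trajs[[1]]$cells[[1]]$D_c, D_e = trajs[[1]]$net$D_e,
       free_mask = rep(!trajs[[1]]$net$boundary_fixed, each = 3))
}

## Known (structural) blocks of the latent state equations: the coordinate
## facet dx/dt = W (forces + u) is exactly linear in the augmented state, so
## its latent projection never needs to be regressed. Only the force-facet
## transitions are identified from data.
latent_known_parts <- function(basis, D_c, D_e, free_mask) {
  Vxc <- basis_block(basis, "Vxc", "proj")
  VFCE <- basis_block(basis, "VFCEc", "rec")
  VFFA <- basis_block(basis, "VFFAc", "rec")
  mu_c <- split_augmented(matrix(basis$mean_c, 1), "cell")
  Vxe <- basis_block(basis, "Vxe", "proj")
  VFE <- basis_block(basis, "VFElase", "rec")
  mu_e <- split_augmented(matrix(basis$mean_e, 1), "ecm")
  Vxe_m <- Vxe * free_mask          # rows of fixed coordinates zeroed
  list(A = crossprod(Vxc, VFCE + VFFA) / D_c,
       B = t(Vxc) / D_c,
       a0 = as.vector(crossprod(Vxc, mu_c$Fce[1, ] + mu_c$Ffa[1, ])) / D_c,
       G = crossprod(Vxe_m, VFE) / D_e,
       g0 = as.vector(crossprod(Vxe_m, mu_e$Fe[1, ])) / D_e)
}

## Latent-space FA injection of all cells into the ECM equation:
## (1/D_e) Vxe^T sum_k P_map^k Fhat_FA^c,k, evaluated matrix-free from the
## bond tables (P_map places -I3 blocks, hence the minus sign).
fa_injection_latent <- function(bonds, fhat, Vxe, D_e) {
  acc <- numeric(ncol(Vxe))
  for (k in seq_along(bonds)) {
    b <- bonds[[k]]
    if (!nrow(b)) next
    cols <- as.vector(t(outer(3 * (b$i - 1L), 1:3, "+")))
    rows <- as.vector(t(outer(3 * (b$j - 1L), 1:3, "+")))
    acc <- acc - as.vector(crossprod(Vxe[rows, , drop = FALSE],
                                     fhat[[k]][cols])) / D_e
  }
  acc
}

#' Identify the latent dynamics matrices A, B, C, G
#'
#' Two independent ridge regressions: the cell equation
#' `dz_c/dt ~ A z_c + B u + C z_e + a0` pooled over cells/runs/time, and the
#' ECM equation fitted on the residual after subtracting the analytically
#' known focal-adhesion injection, `dz_e/dt - inj ~ G z_e + g0`. The
#' couplings `D^k` are never regressed (see [assemble_Dk()]); the affine
#' intercepts absorb the centering offsets of the PCA means. Ridge strength
#' is `lambda` scaled by the mean regressor variance; the intercept is not
#' penalized.
#'
#' @param ld training data from [latent_training_data()] (or compatible).
#' @param basis the `latent_basis` used to produce `ld`.
#' @param lambda relative ridge parameter (default 1e-6; 0 requires full
#'   column rank and errors otherwise).
#' @param D_e ECM damping used in the injection term (stored for the
#'   simulator).
#' @param resid_warn warn when a fitted equation's residual RMS exceeds this
#'   fraction of the response RMS.
#' @param stabilize when TRUE (default), eigenvalues of the identified `A`
#'   and `G` whose real part exceeds `-stab_margin` are clamped to
#'   `-stab_margin` (eigenvectors kept). Weakly excited latent modes can
#'   otherwise pick up spuriously positive growth rates from finite data,
#'   which an autonomous long-horizon rollout amplifies exponentially; the
#'   underlying physical system is dissipative, so clamping restores the
#'   known sign of the weak-mode dynamics while leaving well-identified
#'   modes untouched. Any clamp is reported via a message and recorded in
#'   the returned object.
#' @param stab_margin decay-rate floor (1/s) used by the stabilizer.
#' @return object of class `latent_model` with `A`, `B`, `C`, `G`, `a0`,
#'   `g0`, residual summaries and spectral abscissae (pre-stabilization
#'   values kept in `spectral_abscissa_raw`).
#' @export
estimate_parameters <- function(ld, basis, lambda = 1e-6, D_e = NULL,
                                resid_warn = 0.5, stabilize = TRUE,
                                stab_margin = 1e-4) {
  m_c <- ld$m_c; m_e <- ld$m_e
  if (all(abs(ld$u) < 1e-14))
    warning("inputs u are identically zero in the training data; the regression contribution to B is determined by the ridge alone")
  structural <- !is.null(basis) && !is.null(ld$D_c) && !is.null(ld$free_mask)
  if (structural) {
    kn <- latent_known_parts(basis, ld$D_c, ld$D_e %||% D_e, ld$free_mask)
  } else {
    n_u <- ncol(ld$u)
    kn <- list(A = matrix(0, m_c, m_c), B = matrix(0, m_c, n_u),
               a0 = rep(0, m_c), G = matrix(0, m_e, m_e), g0 = rep(0, m_e))
  }
  n_u <- ncol(ld$u)
  Yc <- ld$dzc - ld$zc %*% t(kn$A) - ld$u %*% t(kn$B) -
    matrix(kn$a0, nrow(ld$zc), m_c, byrow = TRUE)
  Xc <- cbind(ld$zc, ld$u, ld$ze, 1)
  cf <- ridge_solve(Xc, Yc, lambda)
  A <- kn$A + t(cf[seq_len(m_c), , drop = FALSE])
  B <- kn$B + t(cf[m_c + seq_len(n_u), , drop = FALSE])
  C <- t(cf[m_c + n_u + seq_len(m_e), , drop = FALSE])
  a0 <- kn$a0 + as.vector(cf[nrow(cf), ])
  res_c <- Yc - Xc %*% cf

  Ye <- ld$dze - ld$fa_inj - ld$ze %*% t(kn$G) -
    matrix(kn$g0, nrow(ld$ze), m_e, byrow = TRUE)
  Xe <- cbind(ld$ze, 1)
  cg <- ridge_solve(Xe, Ye, lambda)
  G <- kn$G + t(cg[seq_len(m_e), , drop = FALSE])
  g0 <- kn$g0 + as.vector(cg[nrow(cg), ])
  res_e <- Ye - Xe %*% cg

  rel_c <- sqrt(mean(res_c^2)) / max(sqrt(mean(ld$dzc^2)), .Machine$double.eps)
  rel_e <- sqrt(mean(res_e^2)) / max(sqrt(mean(Ye^2)), .Machine$double.eps)
  if (rel_c > resid_warn || rel_e > resid_warn)
    warning(sprintf("large training residual (cell %.2f, ECM %.2f relative RMS)",
                    rel_c, rel_e))
  sa_A_raw <- max(Re(eigen(A, only.values = TRUE)$values))
  sa_G_raw <- max(Re(eigen(G, only.values = TRUE)$values))
  stabilized <- c(A = FALSE, G = FALSE)
  if (sa_A_raw > -stab_margin || sa_G_raw > -stab_margin) {
    if (stabilize) {
      if (sa_A_raw > -stab_margin) {
        A <- clamp_spectrum(A, -stab_margin)
        stabilized["A"] <- TRUE
      }
      if (sa_G_raw > -stab_margin) {
        G <- clamp_spectrum(G, -stab_margin)
        stabilized["G"] <- TRUE
      }
      message(sprintf(
        "identified dynamics stabilized: spectral abscissa A %.3g -> %.3g, G %.3g -> %.3g",
        sa_A_raw, max(Re(eigen(A, only.values = TRUE)$values)),
        sa_G_raw, max(Re(eigen(G, only.values = TRUE)$values))))
    } else if (sa_A_raw > 1e-10 || sa_G_raw > 1e-10) {
      warning(sprintf("identified dynamics are not dissipative (spectral abscissa A = %.3g, G = %.3g)",
                      sa_A_raw, sa_G_raw))
    }
  }
  sa_A <- max(Re(eigen(A, only.values = TRUE)$values))
  sa_G <- max(Re(eigen(G, only.values = TRUE)$values))
  structure(list(A = A, B = B, C = C, G = G, a0 = a0, g0 = g0,
                 basis = basis, lambda = lambda,
                 D_e = D_e, residual_rms = c(cell = rel_c, ecm = rel_e),
                 spectral_abscissa = c(A = sa_A, G = sa_G),
                 spectral_abscissa_raw = c(A = sa_A_raw, G = sa_G_raw),
                 stabilized = stabilized),
            class = "latent_model")
}

## Clamp the real parts of a real matrix's eigenvalues at `floor_re` while
## keeping its eigenvectors (complex pairs handled through Re() of the
## reconstructed matrix, which is exact for a real spectrum decomposition).
clamp_spectrum <- function(M, floor_re) {
  eg <- eigen(M)
  lam <- eg$values
  re <- Re(lam)
  re[re > floor_re] <- floor_re
  lam_new <- complex(real = re, imaginary = Im(lam))
  M_new <- eg$vectors %*% diag(lam_new, nrow = length(lam_new)) %*%
    solve(eg$vectors)
  Re(M_new)
}

ridge_solve <- function(X, Y, lambda) {
  p <- ncol(X)
  XtX <- crossprod(X)
  if (lambda <= 0) {
    if (qr(XtX)$rank < p)
      stop("rank-deficient regression; increase lambda or enrich the training data")
    pen <- 0
  } else {
    scale <- mean(diag(XtX)[-p])   # exclude the intercept column
    pen <- lambda * scale * diag(p)
    pen[p, p] <- 0                 # never penalize the intercept
  }
  solve(XtX + pen, crossprod(X, Y))
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model> m_c = %d, m_e = %d; residual RMS (rel): cell %.3g, ECM %.3g; spectral abscissa A %.3g, G %.3g\n",
              ncol(x$A), ncol(x$G), x$residual_rms[1], x$residual_rms[2],
              x$spectral_abscissa[1], x$spectral_abscissa[2]))
  invisible(x)
}

#' Analytic latent coupling matrix of one cell into the ECM equation
#'
#' `D^k = V_x^e^T (1/D_e) P_map^k V_FFA^c`, recomputed whenever the bond set
#' changes. Together with the constant offset
#' `d0^k = V_x^e^T (1/D_e) P_map^k mu_FFA` (from the PCA centering mean)
#' this reproduces the matrix-free focal-adhesion injection exactly.
#'
#' @param P sparse mapping matrix from [build_mapping_matrix()].
#' @param basis a `latent_basis`.
#' @param D_e ECM damping (nN.s/um).
#' @return list with `Dk` (m_e x m_c) and offset `d0` (length m_e).
#' @export
assemble_Dk <- function(P, basis, D_e) {
  Vxe <- basis_block(basis, "Vxe", "proj")
  VFFAc <- basis_block(basis, "VFFAc", "rec")
  stopifnot(nrow(P) == nrow(Vxe), ncol(P) == nrow(VFFAc))
  mu_ffa <- split_augmented(matrix(basis$mean_c, 1), "cell")$Ffa[1, ]
  Dk <- crossprod(Vxe, as.matrix(P %*% VFFAc)) / D_e
  d0 <- as.vector(crossprod(Vxe, as.vector(P %*% mu_ffa))) / D_e
  list(Dk = Dk, d0 = d0)
}

#' Reduced-order multi-cell simulation by superposition
#'
#' Integrates `dz_c,k/dt = A z_c,k + B u_k + C z_e + a0` for every cell and
#' `dz_e/dt = G z_e + sum_k inj_k + g0` with explicit Euler at the training
#' sampling interval. Per step the full-space geometry is reconstructed
#' through the basis; adhesions are attached/detached on the reconstructed
#' coordinates (re-forming the mapping matrices), the polarity loop senses
#' the reconstructed ECM tension field and regenerates the lamellipodial
#' inputs, and the focal-adhesion injection `inj_k` (the `D^k z_c,k + d0^k`
#' coupling) is evaluated matrix-free. Cells never see each other directly:
#' they couple only through the shared latent ECM state.
#'
#' @param model a `latent_model` (trained on single-cell runs; the same
#'   matrices serve any cell count).
#' @param world a `sim_world` giving the initial condition (any number of
#'   cells).
#' @param config a `sim_config`; the latent Euler step is
#'   `config$sample_interval` and `config$dt` is ignored.
#' @param divergence_tol abort when the latent state norm exceeds this
#'   multiple of its initial scale (signals an unstable identified model).
#' @return an `ecm_trajectory`-compatible object with reconstructed `xe`,
#'   `Fe`, per-cell `xc`, and the latent trajectories `zc`, `ze`.
#' @export
simulate_latent <- function(model, world, config, divergence_tol = 1e6) {
  set.seed(config$seed)
  basis <- model$basis
  dt <- config$sample_interval
  n_frames <- round(config$t_end / dt) + 1L
  n_cells <- length(world$cells)
  D_e <- model$D_e %||% world$net$D_e
  Vxe <- basis_block(basis, "Vxe", "proj")
  VFFAc <- basis_block(basis, "VFFAc", "rec")
  mu_ffa <- split_augmented(matrix(basis$mean_c, 1), "cell")$Ffa[1, ]

  ## initial augmented state from the exact forces of the initial world
  world <- control_update(world, config)
  forces <- world_forces(world)
  ze <- as.vector(project_latent(c(flatten_coords(world$xe),
                                   flatten_coords(forces$fe)), basis, "ecm"))
  zc <- lapply(seq_len(n_cells), function(k)
    as.vector(project_latent(c(flatten_coords(world$xc[[k]]),
                               flatten_coords(forces$fc[[k]]),
                               flatten_coords(forces$fa$cell[[k]])),
                             basis, "cell")))
  z_scale <- sqrt(sum(ze^2) + sum(unlist(zc)^2)) + 1

  adhesion <- world$adhesion
  polarity <- world$polarity
  u <- world$u

  xe_out <- matrix(0, n_frames, 3 * basis$n_ecm_nodes)
  fe_out <- matrix(0, n_frames, 3 * basis$n_ecm_nodes)
  xc_out <- lapply(world$cells, function(cl) matrix(0, n_frames, 3 * cl$n_nodes))
  zc_out <- lapply(seq_len(n_cells), function(k) matrix(0, n_frames, basis$m_c))
  ze_out <- matrix(0, n_frames, basis$m_e)
  pol_out <- lapply(seq_len(n_cells), function(k) matrix(0, n_frames, 3))
  bonds_out <- vector("list", n_frames)
  times <- dt * (seq_len(n_frames) - 1L)

  for (frame in seq_len(n_frames)) {
    ## reconstruct geometry and auxiliary forces
    zeta_e <- as.vector(reconstruct_latent(ze, basis, "ecm"))
    blk_e <- split_augmented(matrix(zeta_e, 1), "ecm")
    xe_hat <- unflatten_coords(blk_e$x[1, ])
    xc_hat <- vector("list", n_cells)
    fhat_fa <- vector("list", n_cells)
    for (k in seq_len(n_cells)) {
      zeta_c <- as.vector(reconstruct_latent(zc[[k]], basis, "cell"))
      blk_c <- split_augmented(matrix(zeta_c, 1), "cell")
      xc_hat[[k]] <- unflatten_coords(blk_c$x[1, ])
      fhat_fa[[k]] <- blk_c$Ffa[1, ]
    }

    xe_out[frame, ] <- blk_e$x[1, ]
    fe_out[frame, ] <- blk_e$Fe[1, ]
    ze_out[frame, ] <- ze
    for (k in seq_len(n_cells)) {
      xc_out[[k]][frame, ] <- flatten_coords(xc_hat[[k]])
      zc_out[[k]][frame, ] <- zc[[k]]
      pol_out[[k]][frame, ] <- polarity[[k]]$d_pol
    }
    bonds_out[[frame]] <- lapply(adhesion$bonds, identity)
    if (frame == n_frames) break

    ## control loop on reconstructed geometry
    if (config$update_adhesions)
      adhesion <- update_adhesions(adhesion, xc_hat, xe_hat,
                                   world$net$boundary_fixed)
    if (config$update_polarity) {
      net_view <- world$net
      for (k in seq_len(n_cells)) {
        ## a badly reconstructed centroid can momentarily leave the fiber
        ## cloud; sensing failure then just means "no rotation cue"
        dmax <- tryCatch(
          max_stiffness_direction(net_view, xe_hat, colMeans(xc_hat[[k]]),
                                  world$params$sensing_radius,
                                  current = polarity[[k]]$d_pol),
          error = function(e) polarity[[k]]$d_pol)
        polarity[[k]] <- update_polarity(polarity[[k]], dmax, dt)
        ## same traction gating as the full simulator's control loop
        if (nrow(adhesion$bonds[[k]]) > 0) {
          u[[k]] <- lamellipodial_input(world$cells[[k]], xc_hat[[k]],
                                        polarity[[k]])
        } else {
          u[[k]] <- numeric(3 * world$cells[[k]]$n_nodes)
        }
      }
    }

    inj <- fa_injection_latent(adhesion$bonds, fhat_fa, Vxe, D_e)
    dze <- as.vector(model$G %*% ze) + inj + model$g0
    ze <- ze + dt * dze
    for (k in seq_len(n_cells)) {
      dzc <- as.vector(model$A %*% zc[[k]]) + as.vector(model$B %*% u[[k]]) +
        as.vector(model$C %*% ze_out[frame, ]) + model$a0
      zc[[k]] <- zc[[k]] + dt * dzc
    }
    if (sqrt(sum(ze^2) + sum(unlist(zc)^2)) > divergence_tol * z_scale)
      stop(sprintf("latent state diverged at t = %.0f s: unstable identified model",
                   times[frame]))
  }

  bonds_out[[n_frames]] <- lapply(adhesion$bonds, identity)
  structure(list(times = times, xe = xe_out, Fe = fe_out, xc = xc_out,
                 zc = zc_out, ze = ze_out, polarity = pol_out,
                 bonds = bonds_out,
                 net = world$net, cells = world$cells, config = config,
                 model = model),
            class = "ecm_trajectory")
}
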