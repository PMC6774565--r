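## Comparison baselines: global first-order Taylor linearization of the
## elastic/cortical force fields about the initial configuration, and a
## trajectory piecewise-linear (TPWL) model built from local linearizations
## sampled along a training trajectory. Both reuse the full simulator's
## integration and control loops; only the force dispatch changes. The
## focal-adhesion force is linear in the coordinates for a given bond set
## and is always evaluated exactly (the bond set itself still evolves).

#' Central finite-difference Jacobian of a force field
#'
#' @param f function mapping a flattened coordinate vector to a flattened
#'   force vector.
#' @param x0 expansion point (flattened).
#' @param eps relative step (scaled by `1 + |x0|` per coordinate).
#' @param sparse drop entries below `zap` and return a sparse matrix.
#' @param zap absolute zero threshold for sparsification.
#' @return Jacobian matrix (sparse `dgCMatrix` if `sparse`).
#' @export
jacobian_fd <- function(f, x0, eps = 1e-6, sparse = TRUE, zap = 1e-10) {
  n <- length(x0)
  cols <- vector("list", n)
  for (j in seq_len(n)) {
    h <- eps * (1 + abs(x0[j]))
    xp <- x0; xp[j] <- xp[j] + h
    xm <- x0; xm[j] <- xm[j] - h
    cols[[j]] <- (f(xp) - f(xm)) / (2 * h)
  }
  J <- do.call(cbind, cols)
  if (sparse) {
    J[abs(J) < zap] <- 0
    J <- as(J, "CsparseMatrix")
  }
  J
}

#' Globally linearized (first-order Taylor) model of a world
#'
#' Replaces the ECM elastic and cell cortical-elastic force fields by their
#' first-order Taylor expansions about the current (reference)
#' configuration: `F(x) ~ F(xbar) + J(xbar) (x - xbar)`. At the reference
#' the forces equal the nonlinear ones exactly. Focal-adhesion and
#' lamellipodial forces are untouched.
#'
#' @param world a `sim_world` at the reference configuration.
#' @param eps finite-difference step for the Jacobians.
#' @return a `sim_world` with force mode `"taylor"`.
#' @export
taylor_model <- function(world, eps = 1e-6) {
  net <- world$net
  xe0 <- flatten_coords(world$xe)
  fe_fun <- function(x) flatten_coords(ecm_elastic_forces(net, unflatten_coords(x)))
  lin <- list(xe0 = xe0, Fe0 = fe_fun(xe0),
              Je = jacobian_fd(fe_fun, xe0, eps),
              xc0 = list(), Fc0 = list(), Jc = list())
  for (k in seq_along(world$cells)) {
    cl <- world$cells[[k]]
    xc0 <- flatten_coords(world$xc[[k]])
    fc_fun <- function(x) flatten_coords(cortical_elastic_forces(cl, unflatten_coords(x)))
    lin$xc0[[k]] <- xc0
    lin$Fc0[[k]] <- fc_fun(xc0)
    lin$Jc[[k]] <- jacobian_fd(fc_fun, xc0, eps)
  }
  world$force_mode <- "taylor"
  world$linearization <- lin
  world
}

#' Simulate the Taylor-linearized dynamics
#'
#' @param world a `sim_world` (the initial configuration is the expansion
#'   point).
#' @param config a `sim_config`.
#' @param ... passed to [simulate_full()].
#' @return an `ecm_trajectory`.
#' @export
simulate_taylor <- function(world, config, ...) {
  simulate_full(taylor_model(world), config, ...)
}

#' Trajectory piecewise-linear (TPWL) model
#'
#' Selects about `kappa_pts` linearization points along a training
#' trajectory by greedy distance-threshold sampling (a new point is accepted
#' once the trajectory has moved at least `total path length / kappa_pts`
#' away from the last accepted point, in the pooled ECM+cell coordinate
#' metric), computes local force values and Jacobians at each, and blends
#' the local affine models with normalized Gaussian kernel weights in state
#' distance. With a single point the model reduces exactly to the Taylor
#' baseline about that point.
#'
#' @param trajs one training `ecm_trajectory`, or a list of them (points are
#'   then pooled across the trajectories, proportionally to path length).
#' @param world a `sim_world` matching the trajectories' topology.
#' @param kappa_pts number of linearization points.
#' @param bandwidth kernel bandwidth (um, pooled-state distance); default is
#'   the median spacing between consecutive selected points.
#' @param max_active at most this many nearest points contribute per
#'   evaluation (the Gaussian weights of farther points are negligible).
#' @param eps finite-difference step.
#' @return a `sim_world` with force mode `"tpwl"`.
#' @export
tpwl_model <- function(trajs, world, kappa_pts = 100, bandwidth = NULL,
                       max_active = 6, eps = 1e-6) {
  if (inherits(trajs, "ecm_trajectory")) trajs <- list(trajs)
  ## greedy arc-length point selection, pooled over trajectories
  lens <- vapply(trajs, function(tr) {
    sm <- cbind(tr$xe, do.call(cbind, tr$xc))
    sum(sqrt(rowSums((sm[-1, , drop = FALSE] - sm[-nrow(sm), , drop = FALSE])^2)))
  }, 0)
  thresh <- sum(lens) / kappa_pts
  sel <- list()
  for (r in seq_along(trajs)) {
    tr <- trajs[[r]]
    sm <- cbind(tr$xe, do.call(cbind, tr$xc))
    step_d <- sqrt(rowSums((sm[-1, , drop = FALSE] - sm[-nrow(sm), , drop = FALSE])^2))
    acc <- thresh   # take the first frame of every trajectory
    for (t in seq_len(nrow(sm))) {
      if (acc >= thresh && length(sel) < kappa_pts) {
        sel[[length(sel) + 1L]] <- c(r, t)
        acc <- 0
      }
      if (t <= length(step_d)) acc <- acc + step_d[t]
    }
  }
  net <- trajs[[1]]$net
  cells <- trajs[[1]]$cells
  fe_fun <- function(x) flatten_coords(ecm_elastic_forces(net, unflatten_coords(x)))
  pts <- vector("list", length(sel))
  for (p in seq_along(sel)) {
    tr <- trajs[[sel[[p]][1]]]
    t <- sel[[p]][2]
    xe0 <- tr$xe[t, ]
    entry <- list(state = c(tr$xe[t, ], unlist(lapply(tr$xc, function(m) m[t, ]))),
                  xe0 = xe0, Fe0 = fe_fun(xe0),
                  Je = jacobian_fd(fe_fun, xe0, eps),
                  xc0 = list(), Fc0 = list(), Jc = list())
    for (k in seq_along(cells)) {
      cl <- cells[[k]]
      xc0 <- tr$xc[[k]][t, ]
      fc_fun <- function(x) flatten_coords(cortical_elastic_forces(cl, unflatten_coords(x)))
      entry$xc0[[k]] <- xc0
      entry$Fc0[[k]] <- fc_fun(xc0)
      entry$Jc[[k]] <- jacobian_fd(fc_fun, xc0, eps)
    }
    pts[[p]] <- entry
  }
  if (is.null(bandwidth)) {
    P <- do.call(rbind, lapply(pts, `[[`, "state"))
    if (nrow(P) > 1) {
      bandwidth <- stats::median(sqrt(rowSums((P[-1, , drop = FALSE] -
                                                 P[-nrow(P), , drop = FALSE])^2)))
    } else bandwidth <- 1
  }
  world$force_mode <- "tpwl"
  world$linearization <- list(points = pts, bandwidth = bandwidth,
                              max_active = as.integer(max_active))
  world
}

#' Kernel weights of the TPWL points at a given state
#'
#' Normalized Gaussian weights in pooled state distance: non-negative, sum
#' to one, and monotone decreasing in distance (a state sitting exactly on a
#' linearization point gives that point the largest weight).
#'
#' @param world a `sim_world` with force mode `"tpwl"`.
#' @param state flattened pooled state (ECM then cells); default the world's
#'   current state.
#' @return numeric weight vector over the linearization points.
#' @export
tpwl_weights <- function(world, state = NULL) {
  lin <- world$linearization
  if (is.null(state))
    state <- c(flatten_coords(world$xe),
               unlist(lapply(world$xc, flatten_coords)))
  d2 <- vapply(lin$points, function(p) sum((state - p$state)^2), 0)
  w <- exp(-(d2 - min(d2)) / (2 * lin$bandwidth^2))
  w / sum(w)
}

## Blended TPWL force evaluation (only the top weights contribute).
tpwl_forces <- function(world) {
  lin <- world$linearization
  w <- tpwl_weights(world)
  active <- order(w, decreasing = TRUE)[seq_len(min(lin$max_active, length(w)))]
  w_act <- w[active] / sum(w[active])
  xe <- flatten_coords(world$xe)
  fe <- numeric(length(xe))
  fc <- lapply(world$cells, function(cl) numeric(3 * cl$n_nodes))
  for (idx in seq_along(active)) {
    p <- lin$points[[active[idx]]]
    wi <- w_act[idx]
    fe <- fe + wi * (p$Fe0 + as.vector(p$Je %*% (xe - p$xe0)))
    for (k in seq_along(world$cells)) {
      xc <- flatten_coords(world$xc[[k]])
      fc[[k]] <- fc[[k]] + wi * (p$Fc0[[k]] + as.vector(p$Jc[[k]] %*% (xc - p$xc0[[k]])))
    }
  }
  list(fe = unflatten_coords(fe), fc = lapply(fc, unflatten_coords))
}

#' Simulate the TPWL dynamics
#'
#' @param model a `sim_world` prepared by [tpwl_model()] (holding the
#'   initial configuration).
#' @param config a `sim_config`.
#' @param ... passed to [simulate_full()].
#' @return an `ecm_trajectory`.
#' @export
simulate_tpwl <- function(model, config, ...) {
  stopifnot(model$force_mode == "tpwl")
  simulate_full(model, config, ...)
}
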