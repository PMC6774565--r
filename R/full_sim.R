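## Coupled overdamped dynamics of cells + ECM: explicit Euler integration of
## dx/dt = (sum of forces)/D for every free node, with periodic adhesion,
## polarity and lamellipodial-input updates (the "control" loop).

#' Simulation configuration
#'
#' @param dt integrator time step (s).
#' @param t_end simulated physical time (s).
#' @param sample_interval interval between recorded frames (s); also the
#'   interval of the adhesion/polarity/input update loop.
#' @param seed integer seed controlling every stochastic element of the run.
#' @param update_adhesions,update_polarity logical switches for the
#'   attachment/detachment and polarity/input loops (both TRUE normally;
#'   turned off for controlled numerical experiments).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.1, t_end = 3000, sample_interval = 1,
                       seed = 1L, update_adhesions = TRUE,
                       update_polarity = TRUE) {
  stopifnot(dt > 0, t_end >= dt, sample_interval >= dt)
  rec <- round(sample_interval / dt)
  if (abs(rec * dt - sample_interval) > 1e-9)
    stop("sample_interval must be a multiple of dt")
  structure(list(dt = dt, t_end = t_end, sample_interval = sample_interval,
                 record_every = as.integer(rec), seed = as.integer(seed),
                 update_adhesions = isTRUE(update_adhesions),
                 update_polarity = isTRUE(update_polarity)),
            class = "sim_config")
}

#' Assemble a simulation world
#'
#' @param net an `ecm_network`.
#' @param cells list of `cell_mesh` objects.
#' @param adhesion an `adhesion_state` (defaults to an empty one).
#' @param polarity list of `polarity_state`, one per cell (defaults to
#'   +x-pointing polarities).
#' @param params parameter list.
#' @return object of class `sim_world` holding the mutable coordinates
#'   (`xe`, `xc`), bond state and inputs.
#' @export
sim_world <- function(net, cells = list(), adhesion = NULL, polarity = NULL,
                      params = default_params()) {
  n_cells <- length(cells)
  if (is.null(adhesion)) adhesion <- adhesion_state(n_cells, params)
  stopifnot(adhesion$n_cells == n_cells)
  if (is.null(polarity)) {
    polarity <- replicate(n_cells, polarity_state(params = params),
                          simplify = FALSE)
  }
  structure(list(net = net, cells = cells, adhesion = adhesion,
                 polarity = polarity, params = params,
                 xe = net$nodes, xc = lapply(cells, `[[`, "nodes"),
                 u = lapply(cells, function(cl) numeric(3 * cl$n_nodes)),
                 force_mode = "nonlinear", linearization = NULL),
            class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat(sprintf("<sim_world> %d ECM nodes, %d cell(s), force mode '%s'\n",
              x$net$n_nodes, length(x$cells), x$force_mode))
  invisible(x)
}

## Internal force dispatch: returns the elastic/cortical fields under the
## world's force mode plus the (always exact) focal-adhesion pairs.
world_forces <- function(world) {
  mode <- world$force_mode
  if (mode == "nonlinear") {
    fe <- ecm_elastic_forces(world$net, world$xe)
    fc <- lapply(seq_along(world$cells), function(k)
      cortical_elastic_forces(world$cells[[k]], world$xc[[k]]))
  } else if (mode == "taylor") {
    lin <- world$linearization
    dxe <- flatten_coords(world$xe) - lin$xe0
    fe <- unflatten_coords(lin$Fe0 + as.vector(lin$Je %*% dxe))
    fc <- lapply(seq_along(world$cells), function(k) {
      dxc <- flatten_coords(world$xc[[k]]) - lin$xc0[[k]]
      unflatten_coords(lin$Fc0[[k]] + as.vector(lin$Jc[[k]] %*% dxc))
    })
  } else if (mode == "tpwl") {
    ftp <- tpwl_forces(world)
    fe <- ftp$fe
    fc <- ftp$fc
  } else stop("unknown force mode")
  fa <- fa_forces(world$adhesion, world$xc, world$xe)
  list(fe = fe, fc = fc, fa = fa)
}

## One control update: adhesions, then polarity, then lamellipodial inputs.
control_update <- function(world, config) {
  if (config$update_adhesions) {
    world$adhesion <- update_adhesions(world$adhesion, world$xc, world$xe,
                                       world$net$boundary_fixed)
  }
  if (config$update_polarity && length(world$cells)) {
    for (k in seq_along(world$cells)) {
      centroid <- colMeans(world$xc[[k]])
      dmax <- max_stiffness_direction(world$net, world$xe, centroid,
                                      world$params$sensing_radius,
                                      current = world$polarity[[k]]$d_pol)
      world$polarity[[k]] <- update_polarity(world$polarity[[k]], dmax,
                                             config$sample_interval)
      ## protrusion needs adhesion-borne traction: an unanchored cell would
      ## otherwise translate freely under its own lamellipodial force
      if (nrow(world$adhesion$bonds[[k]]) > 0) {
        world$u[[k]] <- lamellipodial_input(world$cells[[k]], world$xc[[k]],
                                            world$polarity[[k]])
      } else {
        world$u[[k]] <- numeric(3 * world$cells[[k]]$n_nodes)
      }
    }
  }
  world
}

#' Advance the world by one explicit Euler step
#'
#' Positions update as `x <- x + dt * F / D` for every free node (cell nodes:
#' cortical-elastic + focal-adhesion + lamellipodial forces; ECM nodes:
#' elastic + focal-adhesion); boundary-fixed ECM nodes do not move. Adhesion,
#' polarity and input updates are handled by the control loop of
#' [simulate_full()], not here.
#'
#' @param world a `sim_world`.
#' @param dt step (s).
#' @param forces optional precomputed output of the internal force dispatch.
#' @return updated `sim_world`.
#' @export
step_world <- function(world, dt, forces = NULL) {
  if (is.null(forces)) forces <- world_forces(world)
  free <- !world$net$boundary_fixed
  fe_tot <- forces$fe + forces$fa$ecm
  world$xe[free, ] <- world$xe[free, ] +
    (dt / world$net$D_e) * fe_tot[free, , drop = FALSE]
  for (k in seq_along(world$cells)) {
    f <- forces$fc[[k]] + forces$fa$cell[[k]] +
      unflatten_coords(world$u[[k]])
    world$xc[[k]] <- world$xc[[k]] + (dt / world$cells[[k]]$D_c) * f
  }
  if (!all(is.finite(world$xe)))
    stop("non-finite ECM state: time step too large for current stiffness")
  world
}

#' Run the coupled nonlinear simulation
#'
#' Integrates the overdamped dynamics with explicit Euler at `config$dt`,
#' recording state, the exact forces used by the integrator at the recorded
#' instant, inputs and bond tables every `config$sample_interval`. The
#' adhesion / polarity / input loop runs once per sampling interval, after
#' the position updates of that interval (update order: forces, positions,
#' adhesions, polarity, inputs). Fully deterministic for a fixed seed.
#'
#' @param world a `sim_world`.
#' @param config a `sim_config`.
#' @param progress print progress every this many recorded frames (0 = quiet).
#' @return object of class `ecm_trajectory`: `times`, frame matrices `xe`,
#'   `Fe` (T x 3N_e), per-cell lists `xc`, `Fce`, `Ffa`, `u` (T x 3N_c),
#'   `polarity` (T x 3), per-frame `bonds`, plus the initial world and config.
#' @export
simulate_full <- function(world, config, progress = 0) {
  set.seed(config$seed)
  n_steps <- round(config$t_end / config$dt)
  rec <- config$record_every
  n_frames <- n_steps %/% rec + 1L
  n_e <- world$net$n_nodes
  n_cells <- length(world$cells)

  times <- numeric(n_frames)
  xe <- matrix(0, n_frames, 3 * n_e)
  fe <- matrix(0, n_frames, 3 * n_e)
  xc <- lapply(world$cells, function(cl) matrix(0, n_frames, 3 * cl$n_nodes))
  fce <- lapply(world$cells, function(cl) matrix(0, n_frames, 3 * cl$n_nodes))
  ffa <- lapply(world$cells, function(cl) matrix(0, n_frames, 3 * cl$n_nodes))
  uu <- lapply(world$cells, function(cl) matrix(0, n_frames, 3 * cl$n_nodes))
  pol <- lapply(seq_len(n_cells), function(k) matrix(0, n_frames, 3))
  bonds <- vector("list", n_frames)

  ## establish initial bonds/inputs before the first recorded frame
  world <- control_update(world, config)

  record <- function(frame, t, forces) {
    times[frame] <<- t
    xe[frame, ] <<- flatten_coords(world$xe)
    fe[frame, ] <<- flatten_coords(forces$fe)
    for (k in seq_len(n_cells)) {
      xc[[k]][frame, ] <<- flatten_coords(world$xc[[k]])
      fce[[k]][frame, ] <<- flatten_coords(forces$fc[[k]])
      ffa[[k]][frame, ] <<- flatten_coords(forces$fa$cell[[k]])
      uu[[k]][frame, ] <<- world$u[[k]]
      pol[[k]][frame, ] <<- world$polarity[[k]]$d_pol
    }
    bonds[[frame]] <<- lapply(world$adhesion$bonds, identity)
  }

  frame <- 1L
  world0 <- world
  for (s in seq_len(n_steps)) {
    forces <- world_forces(world)
    if (s %% rec == 1L || rec == 1L) {
      ## frame at the *start* of this sampling interval
      record(frame, (s - 1L) * config$dt, forces)
      if (progress > 0 && frame %% progress == 0)
        message(sprintf("t = %.0f s (%d/%d frames)", times[frame], frame, n_frames))
      frame <- frame + 1L
    }
    world <- tryCatch(step_world(world, config$dt, forces),
                      error = function(e)
                        stop(sprintf("step %d (t = %.2f s): %s", s,
                                     s * config$dt, conditionMessage(e)),
                             call. = FALSE))
    if (s %% rec == 0L) world <- control_update(world, config)
  }
  record(frame, n_steps * config$dt, world_forces(world))

  structure(list(times = times, xe = xe, Fe = fe, xc = xc, Fce = fce,
                 Ffa = ffa, u = uu, polarity = pol, bonds = bonds,
                 net = world$net, cells = world$cells, world0 = world0,
                 world_final = world, config = config),
            class = "ecm_trajectory")
}

#' @export
print.ecm_trajectory <- function(x, ...) {
  cat(sprintf("<ecm_trajectory> %d frames (t = %.0f..%.0f s), %d ECM nodes, %d cell(s)\n",
              length(x$times), min(x$times), max(x$times),
              x$net$n_nodes, length(x$cells)))
  invisible(x)
}

#' Total potential energy of a world configuration
#'
#' ECM stretch + bending energy, membrane edge + cortical tension energy,
#' and focal-adhesion spring energy of the current bond set.
#'
#' @param world a `sim_world`.
#' @return scalar energy (nN.um).
#' @export
world_energy <- function(world) {
  e <- ecm_elastic_energy(world$net, world$xe)
  for (k in seq_along(world$cells))
    e <- e + cortical_energy(world$cells[[k]], world$xc[[k]])
  for (k in seq_len(world$adhesion$n_cells)) {
    b <- world$adhesion$bonds[[k]]
    if (nrow(b)) {
      sep <- world$xe[b$j, , drop = FALSE] -
        world$xc[[k]][b$i, , drop = FALSE]
      e <- e + sum(0.5 * world$adhesion$k_FA * b$n_int * rowSums(sep^2))
    }
  }
  e
}
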