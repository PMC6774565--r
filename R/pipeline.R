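## End-to-end convenience layer: single-cell training runs on a fixed ECM,
## basis construction and system identification, mirroring the standard
## workflow (train on single cells, predict multi-cell behavior by
## superposition).

#' Generate single-cell training runs at diverse cell locations
#'
#' Runs the full nonlinear simulator `n_runs` times on the *same* ECM
#' network, each run with a single cell placed at a different seeded
#' location (uniform over the axial core of the domain, keeping the
#' membrane clear of the clamped boundaries) and a random initial polarity.
#'
#' @param net an `ecm_network` (shared across runs).
#' @param n_runs number of runs.
#' @param t_train simulated time per run (s).
#' @param seed base seed; run `n` uses `seed + n`.
#' @param params parameter list.
#' @param dt,sample_interval integrator settings (s).
#' @param progress passed to [simulate_full()].
#' @return list of `ecm_trajectory`.
#' @export
single_cell_training_runs <- function(net, n_runs = 6, t_train = 2400,
                                      seed = 1L, params = default_params(),
                                      dt = 0.1, sample_interval = 1,
                                      progress = 0) {
  dom <- net$domain
  stopifnot(!is.null(dom))
  L <- domain_axis_length(dom)
  margin <- params$cell_radius + dom$boundary_tol + 2
  sample_center <- function() {
    if (dom$type == "cylinder") {
      rmax <- max(dom$radius - params$cell_radius - 2, 0)
      r <- rmax * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
      c(runif(1, margin, L - margin), r * cos(th), r * sin(th))
    } else {
      c(runif(1, margin, L - margin),
        runif(1, params$cell_radius + 2, dom$ly - params$cell_radius - 2),
        runif(1, params$cell_radius + 2, dom$lz - params$cell_radius - 2))
    }
  }
  ## an embedded cell must actually touch fibers: require a minimum number
  ## of free ECM nodes within binding range of the membrane shell
  coverage <- function(center) {
    d_node <- sqrt(colSums((t(net$nodes) - center)^2))
    shell <- abs(d_node - params$cell_radius) <= params$d_bind
    sum(shell & !net$boundary_fixed)
  }
  runs <- vector("list", n_runs)
  for (n in seq_len(n_runs)) {
    center <- withr_seed(seed + n, {
      ctr <- sample_center()
      tries <- 0L
      while (coverage(ctr) < 8 && tries < 50L) {
        ctr <- sample_center()
        tries <- tries + 1L
      }
      ctr
    })
    pol <- withr_seed(seed + n + 5000L,
                      polarity_state(unitize(rnorm(3)), params = params))
    world <- sim_world(net, list(cell_mesh(center, cell_id = 1L,
                                           params = params)),
                       polarity = list(pol), params = params)
    cfg <- sim_config(dt = dt, t_end = t_train,
                      sample_interval = sample_interval, seed = seed + n)
    runs[[n]] <- simulate_full(world, cfg, progress = progress)
  }
  runs
}

#' Train a reduced-order latent model from full nonlinear runs
#'
#' Builds the PCA basis from the pooled augmented trajectories, assembles
#' the latent training data (forward-difference derivatives, analytic FA
#' injection) and identifies A, B, C, G by ridge least squares.
#'
#' @param trajs list of `ecm_trajectory` training runs.
#' @param m_c,m_e retained latent dimensions.
#' @param lambda relative ridge parameter, or `"auto"` to pick from
#'   `lambda_grid` by held-out validation: models are fitted on all runs but
#'   the last, the held-out run is re-simulated in latent space from its
#'   initial condition, and the candidate with the lowest membrane-node
#'   trajectory RMSE wins; the final model is refit on all runs.
#' @param lambda_grid candidate ridge values for `"auto"`.
#' @param basis optionally reuse a precomputed `latent_basis` (e.g. when
#'   sweeping `m` after one full-spectrum decomposition).
#' @param ... passed on to [estimate_parameters()].
#' @return a `latent_model`.
#' @export
train_latent_model <- function(trajs, m_c = 50, m_e = 50, lambda = 1e-6,
                               lambda_grid = 10^seq(-6, -3), basis = NULL,
                               ...) {
  if (is.null(basis)) basis <- build_latent_basis(trajs, m_c, m_e)
  if (identical(lambda, "auto")) {
    if (length(trajs) < 2)
      stop("lambda = 'auto' needs at least two runs (one held out)")
    ho <- trajs[[length(trajs)]]
    ld_tr <- latent_training_data(trajs[-length(trajs)], basis)
    ho_cfg <- sim_config(dt = ho$config$dt, t_end = max(ho$times),
                         sample_interval = ho$config$sample_interval,
                         seed = ho$config$seed)
    score <- vapply(lambda_grid, function(l) {
      m <- suppressWarnings(suppressMessages(
        estimate_parameters(ld_tr, basis, lambda = l,
                            D_e = trajs[[1]]$net$D_e, ...)))
      tryCatch(trajectory_rmse(simulate_latent(m, ho$world0, ho_cfg), ho,
                               "cells"),
               error = function(e) Inf)
    }, 0)
    lambda <- lambda_grid[which.min(score)]
  }
  ld <- latent_training_data(trajs, basis)
  estimate_parameters(ld, basis, lambda = lambda,
                      D_e = trajs[[1]]$net$D_e, ...)
}

#' Truncate a latent basis to smaller retained dimensions
#'
#' Keeps the leading columns (eigenvectors are nested), so a single
#' decomposition at the largest `m` serves a whole dimension sweep.
#'
#' @param basis a `latent_basis`.
#' @param m_c,m_e new (smaller or equal) dimensions.
#' @return a `latent_basis`.
#' @export
truncate_basis <- function(basis, m_c, m_e) {
  stopifnot(m_c <= basis$m_c, m_e <= basis$m_e)
  basis$Vc <- basis$Vc[, seq_len(m_c), drop = FALSE]
  basis$Ve <- basis$Ve[, seq_len(m_e), drop = FALSE]
  basis$lambda_c <- basis$lambda_c[seq_len(m_c)]
  basis$lambda_e <- basis$lambda_e[seq_len(m_e)]
  basis$m_c <- m_c
  basis$m_e <- m_e
  tc <- sum(basis$lambda_full_c); te <- sum(basis$lambda_full_e)
  if (tc > 0) basis$var_retained_c <- sum(basis$lambda_c) / tc
  if (te > 0) basis$var_retained_e <- sum(basis$lambda_e) / te
  basis
}
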