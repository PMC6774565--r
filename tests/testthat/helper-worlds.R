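## Small programmatic fixtures shared across the test files.

## Tiny random network in a short cylinder (~40 nodes), seeded.
tiny_net <- function(seed = 3, params = default_params()) {
  generate_network(cylinder_domain(10, 30, 2), n_fibers = 12,
                   segments_per_fiber = 3, crosslink_radius = 2,
                   seed = seed, params = params)
}

## Two-node axial spring with one end clamped; motion along the axis is an
## exactly linear overdamped relaxation (closed form available).
two_node_spring <- function(k = 1, D = 10) {
  p <- default_params(k_axial = k, k_bend = 0, D_e = D)
  net <- single_fiber_network(c(0, 0, 0), c(1, 0, 0), 1, params = p)
  net$boundary_fixed <- c(TRUE, FALSE)
  net
}

## Central-difference gradient of a scalar function of flattened coords.
num_grad <- function(f, x0, h = 1e-6) {
  g <- numeric(length(x0))
  for (j in seq_along(x0)) {
    xp <- x0; xp[j] <- xp[j] + h
    xm <- x0; xm[j] <- xm[j] - h
    g[j] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

## Small world: tiny network + one cell nestled inside, adhesion-ready.
tiny_world <- function(seed = 3, gamma = 0.3, f_L = 0.5) {
  p <- default_params(cell_radius = 4, gamma = gamma, f_L = f_L,
                      sensing_radius = 12)
  net <- tiny_net(seed, p)
  cl <- cell_mesh(c(15, 0, 0), params = p)
  sim_world(net, list(cl), params = p)
}
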