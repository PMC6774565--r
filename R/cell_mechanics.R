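## Cell membrane mesh, cortical mechanics, polarity dynamics and
## lamellipodial (leading edge) input generation.

#' Construct a triangulated cell membrane mesh
#'
#' The membrane is a closed icosphere (subdivision level from `params`)
#' centred at `center` with rest radius `params$cell_radius`. Mechanics:
#' Hookean springs along triangle edges (rest lengths from the as-built
#' geometry) plus an isotropic cortical tension proportional to the total
#' membrane area, which always contracts the mesh toward smaller area.
#'
#' @param center 3-vector centroid position (um).
#' @param cell_id integer cell identifier.
#' @param params parameter list from [default_params()].
#' @return object of class `cell_mesh` with fields `nodes` (N_c x 3),
#'   `triangles`, `edges`, `rest_edge_lengths`, `rest_area`, `D_c`.
#' @export
cell_mesh <- function(center = c(0, 0, 0), cell_id = 1L,
                      params = default_params()) {
  ico <- icosphere(params$cell_subdiv)
  nodes <- ico$vertices * params$cell_radius
  nodes <- sweep(nodes, 2, center, "+")
  tri <- ico$faces
  edges <- edges_from_triangles(tri)
  d <- nodes[edges[, 2], ] - nodes[edges[, 1], ]
  L0 <- sqrt(rowSums(d * d))
  n <- nrow(nodes)
  n_e <- nrow(edges)
  inc <- sparseMatrix(i = c(edges[, 1], edges[, 2]),
                      j = c(seq_len(n_e), seq_len(n_e)),
                      x = c(rep(1, n_e), rep(-1, n_e)),
                      dims = c(n, n_e))
  mesh <- structure(list(nodes = nodes, triangles = tri, edges = edges,
                         rest_edge_lengths = L0,
                         k_edge = rep(params$k_edge, n_e),
                         gamma = params$gamma, D_c = params$D_c,
                         cell_id = as.integer(cell_id),
                         inc = inc, n_nodes = n),
                    class = "cell_mesh")
  mesh$rest_area <- membrane_area(mesh, nodes)
  mesh
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("<cell_mesh #%d> %d nodes, %d triangles, %d edges, rest area %.1f um^2\n",
              x$cell_id, x$n_nodes, nrow(x$triangles), nrow(x$edges), x$rest_area))
  invisible(x)
}

#' Total membrane area
#' @param cell a `cell_mesh`.
#' @param coords N_c x 3 coordinates (um).
#' @return scalar area (um^2).
#' @export
membrane_area <- function(cell, coords) {
  tri <- cell$triangles
  a <- coords[tri[, 1], , drop = FALSE]
  b <- coords[tri[, 2], , drop = FALSE]
  cc <- coords[tri[, 3], , drop = FALSE]
  n <- cross_rows(b - a, cc - a)
  sum(row_norms(n)) / 2
}

#' Cortical tension and membrane elastic forces
#'
#' Negative gradient of `sum_edges k_edge/2 (l - l0)^2 + gamma * area`.
#' On a closed mesh the nodal forces sum to zero exactly (internal forces).
#'
#' @inheritParams membrane_area
#' @return N_c x 3 matrix of forces (nN).
#' @export
cortical_elastic_forces <- function(cell, coords) {
  stopifnot(nrow(coords) == cell$n_nodes)
  stopifnot_finite(coords)
  d <- coords[cell$edges[, 2], , drop = FALSE] -
    coords[cell$edges[, 1], , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  if (any(len < 1e-9)) stop("collapsed membrane edge")
  g <- (cell$k_edge * (len - cell$rest_edge_lengths) / len) * d
  f <- as.matrix(cell$inc %*% g)
  if (cell$gamma != 0) {
    tri <- cell$triangles
    a <- coords[tri[, 1], , drop = FALSE]
    b <- coords[tri[, 2], , drop = FALSE]
    cc <- coords[tri[, 3], , drop = FALSE]
    n <- cross_rows(b - a, cc - a)
    nn <- row_norms(n)
    if (any(nn < 1e-12)) stop("degenerate (zero-area) membrane triangle")
    nh <- n / nn
    ga <- 0.5 * cross_rows(nh, cc - b)
    gb <- 0.5 * cross_rows(nh, a - cc)
    gc <- 0.5 * cross_rows(nh, b - a)
    grad <- accumulate_rows(cell$n_nodes, c(tri[, 1], tri[, 2], tri[, 3]),
                            rbind(ga, gb, gc))
    f <- f - cell$gamma * grad
  }
  f
}

#' Cortical + edge elastic energy of a membrane configuration
#' @inheritParams membrane_area
#' @return scalar energy (nN.um).
#' @export
cortical_energy <- function(cell, coords) {
  d <- coords[cell$edges[, 2], , drop = FALSE] -
    coords[cell$edges[, 1], , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  sum(0.5 * cell$k_edge * (len - cell$rest_edge_lengths)^2) +
    cell$gamma * membrane_area(cell, coords)
}

## Polarity ------------------------------------------------------------------

#' Construct a cell polarity state
#'
#' @param d_pol unit 3-vector, leading-edge direction.
#' @param params parameter list; uses `kappa`, `alpha_L`, `f_L`.
#' @return object of class `polarity_state`.
#' @export
polarity_state <- function(d_pol = c(1, 0, 0), params = default_params()) {
  structure(list(d_pol = unitize(d_pol), kappa = params$kappa,
                 alpha_L = params$alpha_L, f_L = params$f_L),
            class = "polarity_state")
}

#' Rotate the polarity vector toward the maximum-stiffness direction
#'
#' Advances `d(d_pol)/dt = kappa * d_pol x (d_max x d_pol)` by one explicit
#' Euler step and renormalizes. The right-hand side is orthogonal to `d_pol`,
#' so the rotation stays in the plane spanned by the two vectors; the angle
#' to `d_max` decays at rate `kappa * sin(theta)`. An anti-parallel input is
#' a (valid, unstable) equilibrium and is returned unchanged.
#'
#' @param p a `polarity_state`.
#' @param d_max_stiff unit 3-vector, local maximum-stiffness direction.
#' @param dt time step (s).
#' @return updated `polarity_state`.
#' @export
update_polarity <- function(p, d_max_stiff, dt) {
  stopifnot(dt > 0)
  d <- p$d_pol
  rhs <- p$kappa * cross3(d, cross3(d_max_stiff, d))
  d_new <- d + dt * rhs
  p$d_pol <- d_new / sqrt(sum(d_new^2))
  p
}

#' Lamellipodial force input for one cell
#'
#' Membrane nodes whose direction from the membrane centroid makes an angle
#' `<= alpha_L` with the polarity vector receive an outward force of
#' magnitude `f_L` along the centroid-to-node direction; all other entries
#' are exactly zero. Returned flattened node-major (length 3 N_c), matching
#' the stacked input vector u^k of the collective state equations.
#'
#' @param cell a `cell_mesh`.
#' @param coords current N_c x 3 membrane coordinates (um).
#' @param p a `polarity_state`.
#' @return numeric vector of length `3 * N_c` (nN).
#' @export
lamellipodial_input <- function(cell, coords, p) {
  centroid <- colMeans(coords)
  rel <- sweep(coords, 2, centroid)
  dirs <- unitize_rows(rel)
  cosang <- as.vector(dirs %*% p$d_pol)
  loaded <- cosang >= cos(p$alpha_L)
  f <- matrix(0, cell$n_nodes, 3)
  f[loaded, ] <- p$f_L * dirs[loaded, , drop = FALSE]
  flatten_coords(f)
}

#' Local maximum-stiffness direction in the ECM
#'
#' Estimates the principal direction of the local fiber tension tensor
#' `sum_s |T_s| (u_s u_s^T)` over segments whose midpoint lies within
#' `sensing_radius` of the query point (T_s axial tension, u_s unit segment
#' direction). The sign is chosen toward the higher-tension half-space; ties
#' are broken deterministically (lexicographically largest component vector).
#' If every segment in range is slack the current polarity direction is
#' returned unchanged (no rotation cue). This estimator stands behind a
#' narrow interface so alternative stiffness-sensing rules can be swapped in.
#'
#' @param net an `ecm_network`.
#' @param ecm_coords current ECM coordinates.
#' @param cell_centroid 3-vector query point (um).
#' @param sensing_radius sensing radius (um).
#' @param current unit 3-vector fallback direction (current polarity).
#' @return unit 3-vector.
#' @export
max_stiffness_direction <- function(net, ecm_coords, cell_centroid,
                                    sensing_radius, current = c(1, 0, 0)) {
  mid <- (ecm_coords[net$segments[, 1], , drop = FALSE] +
            ecm_coords[net$segments[, 2], , drop = FALSE]) / 2
  rel <- sweep(mid, 2, cell_centroid)
  within <- rowSums(rel * rel) <= sensing_radius^2
  if (!any(within)) stop("no ECM segment within sensing radius")
  tens <- abs(segment_tensions(net, ecm_coords))[within]
  if (sum(tens) < 1e-12) return(unitize(current))
  d <- ecm_coords[net$segments[within, 2], , drop = FALSE] -
    ecm_coords[net$segments[within, 1], , drop = FALSE]
  u <- unitize_rows(d)
  M <- crossprod(u * sqrt(tens))        # 3x3 tension tensor
  eg <- eigen(M, symmetric = TRUE)
  v <- eg$vectors[, 1]
  ## orient toward the higher-tension half-space
  s <- sum(tens * as.vector(rel[within, , drop = FALSE] %*% v))
  if (abs(s) > 1e-12) {
    if (s < 0) v <- -v
  } else {
    ## deterministic tie-break: lexicographically largest representative
    w <- -v
    if (isTRUE(all(v == w)) || lex_less(v, w)) v <- w
  }
  v
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}
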