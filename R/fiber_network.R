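## ECM fiber network: generation and elastic (stretch + bending) mechanics.
##
## Fibers are polylines of straight segments meeting at crosslink hubs.
## Mechanics: linear axial springs per segment, discrete bending springs at
## interior fiber nodes (penalty on the second-difference "curvature" vector
## relative to its rest value), plus zero-extra crosslink springs joining
## nearby nodes of different fibers. Nodes carry an isotropic damping D_e.

#' Construct an ECM fiber network object
#'
#' Low-level constructor; most users should call [generate_network()] or
#' [single_fiber_network()]. Rest lengths / rest curvatures are taken from
#' the supplied geometry so the as-built configuration is stress free.
#'
#' @param nodes N_e x 3 matrix of node coordinates (um).
#' @param segments integer matrix (n_seg x 2) of node index pairs.
#' @param bend_triples integer matrix (n_tri x 3) of consecutive fiber nodes
#'   (i, j, k) sharing two segments; may have zero rows.
#' @param crosslinks integer matrix (n x 2) of node pairs joining distinct
#'   fibers (already included in `segments`); bookkeeping only.
#' @param boundary_fixed logical mask over nodes; fixed nodes never move.
#' @param domain an [cylinder_domain()] / [box_domain()] descriptor (or NULL).
#' @param params parameter list, see [default_params()]; uses `k_axial`,
#'   `k_bend`, `D_e`.
#' @return object of class `ecm_network`.
#' @export
ecm_network <- function(nodes, segments, bend_triples = NULL, crosslinks = NULL,
                        boundary_fixed = NULL, domain = NULL,
                        params = default_params()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  n <- nrow(nodes)
  segments <- matrix(as.integer(segments), ncol = 2)
  if (any(segments[, 1] == segments[, 2])) stop("segment endpoints must be distinct")
  if (any(segments < 1L) || any(segments > n)) stop("segment index out of range")
  if (is.null(bend_triples)) bend_triples <- matrix(integer(0), 0, 3)
  bend_triples <- matrix(as.integer(bend_triples), ncol = 3)
  if (is.null(crosslinks)) crosslinks <- matrix(integer(0), 0, 2)
  crosslinks <- matrix(as.integer(crosslinks), ncol = 2)
  if (is.null(boundary_fixed)) boundary_fixed <- rep(FALSE, n)
  stopifnot(length(boundary_fixed) == n)

  d <- nodes[segments[, 2], , drop = FALSE] - nodes[segments[, 1], , drop = FALSE]
  L0 <- sqrt(rowSums(d * d))
  if (any(L0 <= 1e-9)) stop("zero-length segment in generated geometry")

  ## Sparse incidence operators reused by every force evaluation.
  n_seg <- nrow(segments)
  inc <- sparseMatrix(i = c(segments[, 1], segments[, 2]),
                      j = c(seq_len(n_seg), seq_len(n_seg)),
                      x = c(rep(1, n_seg), rep(-1, n_seg)),
                      dims = c(n, n_seg))
  n_tri <- nrow(bend_triples)
  if (n_tri > 0) {
    S <- sparseMatrix(i = rep(seq_len(n_tri), 3),
                      j = as.vector(bend_triples),
                      x = rep(c(1, -2, 1), each = n_tri),
                      dims = c(n_tri, n))
    C0 <- as.matrix(S %*% nodes)
  } else {
    S <- NULL
    C0 <- matrix(0, 0, 3)
  }

  structure(list(nodes = nodes, segments = segments, bend_triples = bend_triples,
                 crosslinks = crosslinks, boundary_fixed = boundary_fixed,
                 domain = domain, L0 = L0,
                 k_axial = rep(params$k_axial, n_seg),
                 k_bend = rep(params$k_bend, n_tri),
                 D_e = params$D_e,
                 inc = inc, S = S, C0 = C0,
                 n_nodes = n),
            class = "ecm_network")
}

#' @export
print.ecm_network <- function(x, ...) {
  cat(sprintf("<ecm_network> %d nodes, %d segments, %d bend triples, %d crosslinks, %d fixed\n",
              x$n_nodes, nrow(x$segments), nrow(x$bend_triples),
              nrow(x$crosslinks), sum(x$boundary_fixed)))
  invisible(x)
}

#' Single straight fiber (mainly for tests and worked examples)
#'
#' @param from,to endpoints (3-vectors, um).
#' @param n_segments number of straight segments.
#' @inheritParams ecm_network
#' @return `ecm_network` with `n_segments + 1` nodes and
#'   `n_segments - 1` bend triples.
#' @export
single_fiber_network <- function(from, to, n_segments, params = default_params()) {
  stopifnot(n_segments >= 1)
  t <- seq(0, 1, length.out = n_segments + 1)
  nodes <- outer(1 - t, from) + outer(t, to)
  segs <- cbind(seq_len(n_segments), seq_len(n_segments) + 1L)
  tri <- if (n_segments >= 2) {
    cbind(seq_len(n_segments - 1L), seq_len(n_segments - 1L) + 1L,
          seq_len(n_segments - 1L) + 2L)
  } else NULL
  ecm_network(nodes, segs, tri, params = params)
}

#' Generate a random cross-linked ECM fiber network
#'
#' Crosslink hub nodes are sampled uniformly in the domain; each hub is then
#' connected to its `knn` nearest hubs by a straight fiber subdivided into
#' `segments_per_fiber` segments, so fibers meet at shared hubs and the
#' network is connected by construction of the nearest-neighbour graph
#' (verified, with bounded re-sampling retries). Additionally, node pairs
#' from different fibers closer than `crosslink_radius` are joined by
#' crosslink springs. The generated configuration is the stress-free rest
#' state. Deterministic for a fixed seed.
#'
#' @param domain an `ecm_domain`.
#' @param n_fibers target number of fibers (hub-to-hub polylines).
#' @param segments_per_fiber straight segments per fiber.
#' @param crosslink_radius proximity radius (um) for extra crosslink springs.
#' @param seed integer RNG seed.
#' @param knn nearest-hub connectivity degree.
#' @param max_retries re-sampling attempts before giving up on connectivity.
#' @inheritParams ecm_network
#' @return `ecm_network`.
#' @export
generate_network <- function(domain, n_fibers = 60, segments_per_fiber = 3,
                             crosslink_radius = 1, seed = 1L, knn = 3,
                             max_retries = 20, params = default_params()) {
  stopifnot(domain_volume(domain) > 0, n_fibers >= 1, segments_per_fiber >= 1)
  n_hubs <- max(4L, as.integer(round(2 * n_fibers / knn)))
  for (attempt in seq_len(max_retries)) {
    net <- withr_seed(seed + attempt - 1L, {
      build_hub_network(domain, n_hubs, knn, segments_per_fiber,
                        crosslink_radius, params)
    })
    if (graph_connected(net$n_nodes, net$segments)) return(net)
  }
  stop("generated network is disconnected after retries: fiber density too low")
}

## Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

build_hub_network <- function(domain, n_hubs, knn, segments_per_fiber,
                              crosslink_radius, params) {
  hubs <- sample_domain_points(domain, n_hubs)
  ## anchor the gel: a fraction of hubs is cast onto each clamped end plane
  n_end <- max(2L, round(0.08 * n_hubs))
  L <- domain_axis_length(domain)
  if (nrow(hubs) >= 4 * n_end) {
    ord <- order(hubs[, 1])
    hubs[ord[seq_len(n_end)], 1] <- 0
    hubs[ord[nrow(hubs) + 1L - seq_len(n_end)], 1] <- L
  }
  ## kNN hub graph (unique undirected pairs)
  D <- as.matrix(stats::dist(hubs))
  diag(D) <- Inf
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_len(n_hubs)) {
    nb <- order(D[i, ])[seq_len(min(knn, n_hubs - 1L))]
    pairs <- rbind(pairs, cbind(pmin(i, nb), pmax(i, nb)))
  }
  pairs <- unique(pairs)

  nodes <- hubs
  segs <- NULL
  tris <- NULL
  fiber_id <- rep(0L, n_hubs)       # 0 = hub (shared); >0 = interior of fiber f
  spf <- segments_per_fiber
  for (f in seq_len(nrow(pairs))) {
    a <- pairs[f, 1]; b <- pairs[f, 2]
    if (spf == 1L) {
      chain <- c(a, b)
    } else {
      tt <- seq(0, 1, length.out = spf + 1)[2:spf]
      interior <- outer(1 - tt, hubs[a, ]) + outer(tt, hubs[b, ])
      i0 <- nrow(nodes)
      nodes <- rbind(nodes, interior)
      fiber_id <- c(fiber_id, rep(f, spf - 1L))
      chain <- c(a, i0 + seq_len(spf - 1L), b)
    }
    segs <- rbind(segs, cbind(chain[-length(chain)], chain[-1]))
    if (length(chain) >= 3) {
      m <- length(chain) - 2L
      tris <- rbind(tris, cbind(chain[seq_len(m)], chain[seq_len(m) + 1L],
                                chain[seq_len(m) + 2L]))
    }
  }

  ## proximity crosslinks between nodes of different fibers
  xl <- NULL
  if (crosslink_radius > 0) {
    Dn <- as.matrix(stats::dist(nodes))
    cand <- which(Dn < crosslink_radius & upper.tri(Dn), arr.ind = TRUE)
    if (nrow(cand)) {
      keep <- fiber_id[cand[, 1]] != fiber_id[cand[, 2]] |
        (fiber_id[cand[, 1]] == 0L & fiber_id[cand[, 2]] == 0L)
      ## drop pairs that are already direct segments
      seg_key <- paste(pmin(segs[, 1], segs[, 2]), pmax(segs[, 1], segs[, 2]))
      cand_key <- paste(pmin(cand[, 1], cand[, 2]), pmax(cand[, 1], cand[, 2]))
      keep <- keep & !(cand_key %in% seg_key)
      xl <- cand[keep, , drop = FALSE]
      if (nrow(xl)) segs <- rbind(segs, xl)
    }
  }

  ecm_network(nodes, segs, tris, crosslinks = xl,
              boundary_fixed = boundary_mask(domain, nodes),
              domain = domain, params = params)
}

#' Elastic forces of the ECM network
#'
#' Returns the negative gradient of the total stretch + bending energy at
#' the supplied configuration: per-segment Hookean axial restoring forces and
#' bending penalty forces at interior fiber nodes. Zero at the rest
#' configuration; equal and opposite within every segment (net force over an
#' isolated network is exactly zero).
#'
#' @param net an `ecm_network`.
#' @param coords N_e x 3 coordinate matrix (um).
#' @return N_e x 3 matrix of forces (nN).
#' @export
ecm_elastic_forces <- function(net, coords) {
  stopifnot(nrow(coords) == net$n_nodes)
  stopifnot_finite(coords)
  d <- coords[net$segments[, 2], , drop = FALSE] -
    coords[net$segments[, 1], , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  if (any(len < 1e-8)) stop("collapsed segment (length below tolerance)")
  g <- (net$k_axial * (len - net$L0) / len) * d   # force on node i, toward j when taut
  f <- as.matrix(net$inc %*% g)
  if (!is.null(net$S)) {
    cvec <- as.matrix(net$S %*% coords) - net$C0
    f <- f - as.matrix(Matrix::t(net$S) %*% (net$k_bend * cvec))
  }
  f
}

#' Total elastic energy of the ECM network
#'
#' @inheritParams ecm_elastic_forces
#' @return scalar energy (nN.um).
#' @export
ecm_elastic_energy <- function(net, coords) {
  d <- coords[net$segments[, 2], , drop = FALSE] -
    coords[net$segments[, 1], , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  e <- sum(0.5 * net$k_axial * (len - net$L0)^2)
  if (!is.null(net$S)) {
    cvec <- as.matrix(net$S %*% coords) - net$C0
    e <- e + sum(0.5 * net$k_bend * rowSums(cvec * cvec))
  }
  e
}

#' Axial segment tensions
#'
#' Positive for stretched (taut) segments, negative for compressed ones.
#'
#' @inheritParams ecm_elastic_forces
#' @return numeric vector, one tension (nN) per segment.
#' @export
segment_tensions <- function(net, coords) {
  d <- coords[net$segments[, 2], , drop = FALSE] -
    coords[net$segments[, 1], , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  net$k_axial * (len - net$L0)
}
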