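## Domain descriptors and mesh primitives.

#' Cylindrical simulation domain
#'
#' The cylinder axis runs along +x from `x = 0` to `x = length`. The two flat
#' end planes are the mechanically constrained boundaries: ECM nodes within
#' `boundary_tol` of either plane are flagged fixed and never move.
#'
#' @param radius cylinder radius (um).
#' @param length cylinder length along the x axis (um).
#' @param boundary_tol distance from an end plane (um) within which nodes are
#'   treated as clamped.
#' @return an object of class `ecm_domain`.
#' @export
cylinder_domain <- function(radius = 20, length = 100, boundary_tol = 3) {
  stopifnot(radius > 0, length > 0, boundary_tol >= 0)
  structure(list(type = "cylinder", radius = radius, length = length,
                 boundary_tol = boundary_tol),
            class = "ecm_domain")
}

#' Rectangular-box simulation domain
#'
#' The box spans `[0, lx] x [0, ly] x [0, lz]`. The two faces normal to x
#' (`x = 0` and `x = lx`) are the constrained boundaries.
#'
#' @param lx,ly,lz box edge lengths (um).
#' @param boundary_tol clamping tolerance at the x faces (um).
#' @return an object of class `ecm_domain`.
#' @export
box_domain <- function(lx = 250, ly = 100, lz = 50, boundary_tol = 3) {
  stopifnot(lx > 0, ly > 0, lz > 0, boundary_tol >= 0)
  structure(list(type = "box", lx = lx, ly = ly, lz = lz,
                 boundary_tol = boundary_tol),
            class = "ecm_domain")
}

domain_volume <- function(domain) {
  switch(domain$type,
         cylinder = pi * domain$radius^2 * domain$length,
         box = domain$lx * domain$ly * domain$lz,
         stop("unknown domain type"))
}

## Uniform point sampling inside a domain (uses the current RNG stream).
sample_domain_points <- function(domain, n) {
  if (domain$type == "cylinder") {
    x <- runif(n, 0, domain$length)
    r <- domain$radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    cbind(x, r * cos(th), r * sin(th))
  } else {
    cbind(runif(n, 0, domain$lx), runif(n, 0, domain$ly), runif(n, 0, domain$lz))
  }
}

domain_axis_length <- function(domain) {
  switch(domain$type, cylinder = domain$length, box = domain$lx)
}

boundary_mask <- function(domain, nodes) {
  L <- domain_axis_length(domain)
  nodes[, 1] <= domain$boundary_tol | nodes[, 1] >= L - domain$boundary_tol
}

## Icosphere membrane mesh ---------------------------------------------------

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_sphere <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  edge_key <- function(i, j) paste(min(i, j), max(i, j))
  midpoint <- new.env(parent = emptyenv())
  get_mid <- function(i, j) {
    key <- edge_key(i, j)
    idx <- midpoint[[key]]
    if (is.null(idx)) {
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      idx <- nrow(v)
      midpoint[[key]] <- idx
    }
    idx
  }
  newf <- matrix(0L, nrow(f) * 4, 3)
  r <- 0L
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
    newf[r + 1L, ] <- c(a, ab, ca)
    newf[r + 2L, ] <- c(b, bc, ab)
    newf[r + 3L, ] <- c(cc, ca, bc)
    newf[r + 4L, ] <- c(ab, bc, ca)
    r <- r + 4L
  }
  list(vertices = v, faces = newf)
}

#' Triangulated icosphere
#'
#' @param subdiv number of recursive subdivisions of the icosahedron
#'   (0 gives 12 vertices, 1 gives 42, 2 gives 162).
#' @return list with unit-sphere `vertices` (n x 3) and `faces` (m x 3).
#' @keywords internal
icosphere <- function(subdiv = 1) {
  mesh <- icosahedron()
  for (i in seq_len(subdiv)) mesh <- subdivide_sphere(mesh)
  mesh
}

edges_from_triangles <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}
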