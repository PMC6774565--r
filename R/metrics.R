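## Quantitative comparison of trajectories and compaction read-outs.

#' Volume of the convex hull of a 3-D point cloud
#'
#' Direct facet-enumeration hull: a triple of points spans a hull facet when
#' every other point lies on one side of its plane; the volume is the sum of
#' signed tetrahedra from the centroid over the facets. Intended for the
#' modest per-slice point counts of the compaction metrics (the cost grows
#' as n^3 triples); inputs larger than `max_points` are thinned
#' deterministically. Degenerate (rank < 3) clouds have zero volume.
#'
#' @param pts n x 3 matrix.
#' @param tol coplanarity tolerance (um).
#' @param max_points thinning threshold.
#' @return scalar volume (um^3).
#' @export
convex_hull_volume <- function(pts, tol = 1e-9, max_points = 120) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 4) return(0)
  if (n > max_points)
    pts <- pts[round(seq(1, n, length.out = max_points)), , drop = FALSE]
  n <- nrow(pts)
  ctr <- colMeans(pts)
  trip <- t(utils::combn(n, 3))
  a <- pts[trip[, 1], , drop = FALSE]
  b <- pts[trip[, 2], , drop = FALSE]
  cc <- pts[trip[, 3], , drop = FALSE]
  nrm <- cross_rows(b - a, cc - a)
  keep <- row_norms(nrm) > tol
  vol <- 0
  s <- pts %*% t(nrm[keep, , drop = FALSE]) -
    matrix(rowSums(nrm[keep, , drop = FALSE] * a[keep, , drop = FALSE]),
           n, sum(keep), byrow = TRUE)
  is_facet <- colSums(s > tol) == 0 | colSums(s < -tol) == 0
  if (!any(is_facet)) return(0)
  ka <- a[keep, , drop = FALSE][is_facet, , drop = FALSE]
  kb <- b[keep, , drop = FALSE][is_facet, , drop = FALSE]
  kc <- cc[keep, , drop = FALSE][is_facet, , drop = FALSE]
  ## several coplanar triples can support the same geometric facet; volume
  ## is summed once per distinct supporting plane.
  sum_facet_volume(pts, ka, kb, kc, ctr, tol)
}

## Robust volume: decompose each hull facet's supporting plane once, fan-
## triangulate the points on that plane, and sum centroid tetrahedra.
sum_facet_volume <- function(pts, ka, kb, kc, ctr, tol) {
  if (!nrow(ka)) return(0)
  nrm <- cross_rows(kb - ka, kc - ka)
  nh <- nrm / row_norms(nrm)
  off <- rowSums(nh * ka)
  ## orient outward (centroid below plane)
  below <- (nh %*% ctr - off) > 0
  nh[below, ] <- -nh[below, , drop = FALSE]
  off[below] <- -off[below]
  key <- paste(round(nh[, 1], 6), round(nh[, 2], 6), round(nh[, 3], 6),
               round(off, 6))
  uq <- !duplicated(key)
  vol <- 0
  for (f in which(uq)) {
    on_plane <- abs(pts %*% nh[f, ] - off[f]) <= max(tol, 1e-7)
    ppts <- pts[on_plane, , drop = FALSE]
    if (nrow(ppts) < 3) next
    ## order points around the facet centroid and fan-triangulate
    fc <- colMeans(ppts)
    e1 <- ppts[1, ] - fc
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(nh[f, ], e1)
    ang <- atan2((ppts - matrix(fc, nrow(ppts), 3, byrow = TRUE)) %*% e2,
                 (ppts - matrix(fc, nrow(ppts), 3, byrow = TRUE)) %*% e1)
    ord <- order(ang)
    ppts <- ppts[ord, , drop = FALSE]
    np <- nrow(ppts)
    idx2 <- c(2:np, 1)
    tet <- abs(rowSums(cross_rows(ppts[idx2, , drop = FALSE] - ppts,
                                  matrix(ctr, np, 3, byrow = TRUE) - ppts) *
                         (matrix(fc, np, 3, byrow = TRUE) - ppts))) / 6
    vol <- vol + sum(tet)
  }
  vol
}

#' Root-mean-square error between two aligned trajectories
#'
#' Square root of the mean (over nodes and frames) squared Euclidean
#' distance between corresponding node positions.
#'
#' @param traj_a,traj_b `ecm_trajectory` objects with identical frame times
#'   and node correspondence.
#' @param entity `"all"`, `"ecm"` or `"cells"`.
#' @return scalar RMSE (um).
#' @export
trajectory_rmse <- function(traj_a, traj_b, entity = c("all", "ecm", "cells")) {
  entity <- match.arg(entity)
  if (length(traj_a$times) != length(traj_b$times) ||
      max(abs(traj_a$times - traj_b$times)) > 1e-9)
    stop("trajectories have mismatched frames")
  parts <- list(); weights <- list()
  if (entity %in% c("all", "ecm")) {
    d <- traj_a$xe - traj_b$xe
    parts$ecm <- sum(d^2) / (nrow(d) * ncol(d) / 3)
    weights$ecm <- ncol(d) / 3
  }
  if (entity %in% c("all", "cells")) {
    stopifnot(length(traj_a$xc) == length(traj_b$xc))
    s <- 0; n <- 0
    for (k in seq_along(traj_a$xc)) {
      d <- traj_a$xc[[k]] - traj_b$xc[[k]]
      s <- s + sum(d^2) / nrow(d)
      n <- n + ncol(d) / 3
    }
    parts$cells <- s / n
    weights$cells <- n
  }
  w <- unlist(weights)
  sqrt(sum(unlist(parts) * w) / sum(w))
}

#' Slice-wise ECM compaction profile
#'
#' Subdivides the domain along its longitudinal (x) axis into slices of
#' `slice_thickness`, assigns ECM nodes to slices by their *initial*
#' (material) axial position, and tracks the convex-hull volume of each
#' material slice through time, normalized by its initial value.
#'
#' @param traj an `ecm_trajectory`.
#' @param slice_thickness slice thickness (um, default 10).
#' @param times subset of frame times to evaluate (default all).
#' @return object of class `compaction_profile`: data.frame `profile` with
#'   columns `time`, `slice`, `x_mid`, `volume`, `norm_volume`, and the
#'   slice boundaries.
#' @export
compaction_profile <- function(traj, slice_thickness = 10, times = NULL) {
  domain <- traj$net$domain
  if (is.null(domain)) stop("trajectory network carries no domain metadata")
  L <- domain_axis_length(domain)
  breaks <- seq(0, L, by = slice_thickness)
  if (abs(breaks[length(breaks)] - L) > 1e-9) breaks <- c(breaks, L)
  x0 <- unflatten_coords(traj$xe[1, ])
  slice_of <- cut(pmin(pmax(x0[, 1], 0), L - 1e-9), breaks,
                  labels = FALSE, include.lowest = TRUE)
  if (is.null(times)) times <- traj$times
  frames <- match(times, traj$times)
  if (anyNA(frames)) stop("requested times not present in trajectory")
  n_slices <- length(breaks) - 1L
  v0 <- numeric(n_slices)
  rows <- list()
  for (s in seq_len(n_slices)) {
    sel <- which(slice_of == s)
    if (length(sel) < 4)
      stop(sprintf("slice %d contains %d nodes (< 4 non-coplanar needed)",
                   s, length(sel)))
    v0[s] <- convex_hull_volume(x0[sel, , drop = FALSE])
    if (v0[s] <= 0)
      stop(sprintf("slice %d has degenerate (coplanar) initial geometry", s))
  }
  for (fi in seq_along(frames)) {
    xt <- unflatten_coords(traj$xe[frames[fi], ])
    for (s in seq_len(n_slices)) {
      sel <- which(slice_of == s)
      v <- convex_hull_volume(xt[sel, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        time = times[fi], slice = s,
        x_mid = (breaks[s] + breaks[s + 1]) / 2,
        volume = v, norm_volume = v / v0[s])
    }
  }
  structure(list(profile = do.call(rbind, rows), breaks = breaks,
                 slice_of = slice_of),
            class = "compaction_profile")
}

#' @export
print.compaction_profile <- function(x, ...) {
  p <- x$profile
  last <- p[p$time == max(p$time), ]
  cat(sprintf("<compaction_profile> %d slices, t = %.0f..%.0f s; final V/V0: %s\n",
              length(x$breaks) - 1L, min(p$time), max(p$time),
              paste(sprintf("%.2f", last$norm_volume), collapse = " ")))
  invisible(x)
}

#' Total normalized ECM volume shrinkage
#'
#' `1 - sum_s V_s(t) / sum_s V_s(0)` over the material slices of a
#' [compaction_profile()]; 0 for an undeformed gel.
#'
#' @param profile a `compaction_profile`.
#' @param time frame time at which to evaluate (default final).
#' @return scalar shrinkage fraction.
#' @export
total_shrinkage <- function(profile, time = NULL) {
  p <- profile$profile
  if (is.null(time)) time <- max(p$time)
  pt <- p[abs(p$time - time) < 1e-9, ]
  if (!nrow(pt)) stop("time not present in profile")
  p0 <- p[p$time == min(p$time), ]
  1 - sum(pt$volume) / sum(p0$volume / p0$norm_volume)
}

#' Mean ECM elastic force magnitude in an axial region
#'
#' Average over ECM nodes whose *initial* axial position lies in
#' `region = c(x_min, x_max)` of the per-node elastic force magnitude, per
#' frame.
#'
#' @param traj an `ecm_trajectory` (must carry the `Fe` channel).
#' @param region numeric length-2 axial interval (um).
#' @return data.frame with `time` and `mean_force` (nN).
#' @export
intercell_elastic_force <- function(traj, region) {
  stopifnot(length(region) == 2, region[2] > region[1])
  x0 <- unflatten_coords(traj$xe[1, ])
  sel <- which(x0[, 1] >= region[1] & x0[, 1] <= region[2])
  if (!length(sel)) stop("no ECM node in the requested region")
  idx <- as.vector(t(outer(3 * (sel - 1L), 1:3, "+")))
  mf <- vapply(seq_along(traj$times), function(t) {
    f <- matrix(traj$Fe[t, idx], ncol = 3, byrow = TRUE)
    mean(row_norms(f))
  }, 0)
  data.frame(time = traj$times, mean_force = mf)
}

#' Maximum displacement over an ECM node subset
#'
#' Per frame, the maximum displacement from the initial position over the
#' given nodes (e.g. the free lateral edge of a gel).
#'
#' @param traj an `ecm_trajectory`.
#' @param edge_nodes integer vector of ECM node indices.
#' @return data.frame with `time` and `max_disp` (um).
#' @export
max_edge_displacement <- function(traj, edge_nodes) {
  stopifnot(length(edge_nodes) >= 1)
  idx <- as.vector(t(outer(3 * (edge_nodes - 1L), 1:3, "+")))
  x0 <- traj$xe[1, idx]
  md <- vapply(seq_along(traj$times), function(t) {
    d <- matrix(traj$xe[t, idx] - x0, ncol = 3, byrow = TRUE)
    max(row_norms(d))
  }, 0)
  data.frame(time = traj$times, max_disp = md)
}
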