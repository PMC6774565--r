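## Focal adhesions: bond bookkeeping, paired forces, mapping matrices.
##
## Each bond links cell-membrane node i of cell k to ECM node j and acts as a
## zero-rest-length linear spring of stiffness k_FA * n_int. Forces come in
## equal-and-opposite pairs (cell node pulled toward ECM node and vice
## versa), so the global focal-adhesion force sum is exactly zero. At most
## one bond per cell node, and an ECM node is bound by at most one cell.

#' Construct an adhesion state
#'
#' @param n_cells number of cells tracked.
#' @param params parameter list; uses `k_FA`, `n_int`, `d_bind`, `d_break`,
#'   `p_on`.
#' @return object of class `adhesion_state`; `bonds` is a list (one data
#'   frame per cell) with columns `i` (cell node), `j` (ECM node),
#'   `n_int` (bound integrin count).
#' @export
adhesion_state <- function(n_cells = 1L, params = default_params()) {
  stopifnot(params$d_break > params$d_bind, params$d_bind > 0)
  empty <- data.frame(i = integer(0), j = integer(0), n_int = integer(0))
  structure(list(bonds = rep(list(empty), n_cells),
                 k_FA = params$k_FA, n_int = as.integer(params$n_int),
                 d_bind = params$d_bind, d_break = params$d_break,
                 p_on = params$p_on, n_cells = as.integer(n_cells)),
            class = "adhesion_state")
}

#' @export
print.adhesion_state <- function(x, ...) {
  cat(sprintf("<adhesion_state> %d cell(s); bonds per cell: %s\n",
              x$n_cells, paste(vapply(x$bonds, nrow, 1L), collapse = ", ")))
  invisible(x)
}

#' Paired focal-adhesion forces
#'
#' Per bond `(i, j)` of cell `k`, the cell node receives
#' `k_FA * n_int * (x_j^e - x_i^c)` and the ECM node receives its negation.
#' The ECM output equals `sum_k P_map^k F_FA^c,k` exactly (see
#' [build_mapping_matrix()]).
#'
#' @param state an `adhesion_state`.
#' @param cell_coords list of N_c x 3 matrices, one per cell.
#' @param ecm_coords N_e x 3 matrix.
#' @return list with `cell` (list of N_c x 3 force matrices, nN) and
#'   `ecm` (N_e x 3 force matrix, nN).
#' @export
fa_forces <- function(state, cell_coords, ecm_coords) {
  n_e <- nrow(ecm_coords)
  f_ecm <- matrix(0, n_e, 3)
  f_cell <- vector("list", state$n_cells)
  for (k in seq_len(state$n_cells)) {
    xc <- cell_coords[[k]]
    fk <- matrix(0, nrow(xc), 3)
    b <- state$bonds[[k]]
    if (nrow(b)) {
      sep <- ecm_coords[b$j, , drop = FALSE] - xc[b$i, , drop = FALSE]
      fb <- state$k_FA * b$n_int * sep
      fk[b$i, ] <- fk[b$i, ] + fb
      f_ecm <- f_ecm - accumulate_rows(n_e, b$j, fb)
    }
    f_cell[[k]] <- fk
  }
  list(cell = f_cell, ecm = f_ecm)
}

#' Sparse mapping matrix P_map^k from cell FA forces to ECM FA forces
#'
#' For each bond `(i, j)` of cell `k` the 3 x 3 block at block-row `j`,
#' block-column `i` is `-I3`; all other entries are zero, so all elements
#' are in `{0, -1}`. `P_map^k %*% F_FA^c,k` (flattened node-major) equals the
#' ECM focal-adhesion force contribution of cell `k`.
#'
#' @param state an `adhesion_state`.
#' @param k cell index.
#' @param n_ecm,n_cell_nodes node counts N_e and N_c.
#' @return sparse `3 N_e x 3 N_c` matrix (class `dgCMatrix`).
#' @export
build_mapping_matrix <- function(state, k, n_ecm, n_cell_nodes) {
  b <- state$bonds[[k]]
  all_j <- unlist(lapply(state$bonds, `[[`, "j"))
  if (anyDuplicated(all_j)) stop("an ECM node is bonded by more than one cell")
  if (!nrow(b)) {
    return(sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                        dims = c(3 * n_ecm, 3 * n_cell_nodes)))
  }
  rows <- as.vector(t(outer(3 * (b$j - 1L), 1:3, "+")))
  cols <- as.vector(t(outer(3 * (b$i - 1L), 1:3, "+")))
  sparseMatrix(i = rows, j = cols, x = rep(-1, length(rows)),
               dims = c(3 * n_ecm, 3 * n_cell_nodes))
}

#' Stochastic attachment / distance-based detachment update
#'
#' Bonds stretched beyond `d_break` detach. Then, cell by cell and in node
#' order, every unbonded membrane node attaches (with probability `p_on`,
#' drawn from the current RNG stream) to the nearest free ECM node within
#' `d_bind`. Boundary-fixed ECM nodes and nodes already bound (by any cell)
#' are skipped, preserving the one-cell-per-ECM-node invariant. Deterministic
#' for a fixed RNG state.
#'
#' @param state an `adhesion_state`.
#' @param cell_coords list of N_c x 3 matrices.
#' @param ecm_coords N_e x 3 matrix.
#' @param boundary_fixed logical mask of clamped ECM nodes (excluded from
#'   binding); default none.
#' @return updated `adhesion_state`.
#' @export
update_adhesions <- function(state, cell_coords, ecm_coords,
                             boundary_fixed = NULL) {
  n_e <- nrow(ecm_coords)
  if (is.null(boundary_fixed)) boundary_fixed <- rep(FALSE, n_e)
  occupied <- rep(FALSE, n_e)
  ## detachment pass
  for (k in seq_len(state$n_cells)) {
    b <- state$bonds[[k]]
    if (nrow(b)) {
      sep <- ecm_coords[b$j, , drop = FALSE] -
        cell_coords[[k]][b$i, , drop = FALSE]
      keep <- sqrt(rowSums(sep * sep)) <= state$d_break
      b <- b[keep, , drop = FALSE]
      state$bonds[[k]] <- b
    }
    occupied[b$j] <- TRUE
  }
  ## attachment pass
  for (k in seq_len(state$n_cells)) {
    b <- state$bonds[[k]]
    xc <- cell_coords[[k]]
    free_nodes <- setdiff(seq_len(nrow(xc)), b$i)
    if (!length(free_nodes)) next
    eligible <- which(!occupied & !boundary_fixed)
    if (!length(eligible)) next
    d2 <- outer(rowSums(xc[free_nodes, , drop = FALSE]^2),
                rowSums(ecm_coords[eligible, , drop = FALSE]^2), "+") -
      2 * xc[free_nodes, , drop = FALSE] %*%
      t(ecm_coords[eligible, , drop = FALSE])
    for (r in seq_along(free_nodes)) {
      jbest <- which.min(d2[r, ])
      if (!length(jbest) || d2[r, jbest] > state$d_bind^2) next
      if (runif(1) <= state$p_on) {
        jn <- eligible[jbest]
        b <- rbind(b, data.frame(i = free_nodes[r], j = jn,
                                 n_int = state$n_int))
        occupied[jn] <- TRUE
        d2[, jbest] <- Inf    # node now taken
      }
    }
    state$bonds[[k]] <- b
  }
  state
}
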