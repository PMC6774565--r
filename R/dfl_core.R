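## Augmented-state machinery: the nonlinear force terms are promoted to
## auxiliary state variables, giving per-cell augmented vectors
## zeta_c = (x^c; F_CortElas^c; F_FA^c) of length 9 N_c and an ECM vector
## zeta_e = (x^e; F_Elas^e) of length 6 N_e. Lamellipodial inputs u stay
## outside the augmented space (they are inputs), and the ECM FA force is
## excluded from zeta_e because it is determined by the cells through the
## mapping matrices.

#' Assemble augmented-state trajectories from a simulation
#'
#' Stacks, per frame, the coordinate and force blocks in the fixed order
#' (x; F_CortElas; F_FA) for each cell and (x^e; F_Elas^e) for the ECM.
#' The operation is lossless: [split_augmented()] recovers the original
#' blocks bit-exactly.
#'
#' @param traj an `ecm_trajectory`.
#' @return list with `zeta_c` (list per cell of T x 9N_c matrices) and
#'   `zeta_e` (T x 6N_e matrix).
#' @export
build_augmented <- function(traj) {
  if (is.null(traj$Fce) || is.null(traj$Ffa) || is.null(traj$Fe))
    stop("trajectory is missing force channels")
  zeta_c <- lapply(seq_along(traj$cells), function(k)
    cbind(traj$xc[[k]], traj$Fce[[k]], traj$Ffa[[k]]))
  zeta_e <- cbind(traj$xe, traj$Fe)
  list(zeta_c = zeta_c, zeta_e = zeta_e)
}

#' Split augmented vectors back into their blocks
#'
#' @param zeta matrix of augmented row vectors (or a single vector).
#' @param entity `"cell"` (three equal blocks) or `"ecm"` (two equal blocks).
#' @return named list of block matrices.
#' @export
split_augmented <- function(zeta, entity = c("cell", "ecm")) {
  entity <- match.arg(entity)
  if (is.null(dim(zeta))) zeta <- matrix(zeta, nrow = 1)
  d <- ncol(zeta)
  if (entity == "cell") {
    stopifnot(d %% 3 == 0)
    b <- d / 3
    list(x = zeta[, 1:b, drop = FALSE],
         Fce = zeta[, (b + 1):(2 * b), drop = FALSE],
         Ffa = zeta[, (2 * b + 1):(3 * b), drop = FALSE])
  } else {
    stopifnot(d %% 2 == 0)
    b <- d / 2
    list(x = zeta[, 1:b, drop = FALSE],
         Fe = zeta[, (b + 1):(2 * b), drop = FALSE])
  }
}

#' Pooled covariance of augmented samples
#'
#' Computes `C = (1/n) sum (zeta - mean)(zeta - mean)^T` pooled over the
#' rows of all supplied matrices (cells x runs x time), centering with the
#' global mean over that same pooled index set.
#'
#' @param mats a matrix of row samples, or a list of such matrices.
#' @return list with `C` (symmetric PSD), `mean`, and sample count `n`.
#' @export
augmented_covariance <- function(mats) {
  if (is.matrix(mats)) mats <- list(mats)
  d <- unique(vapply(mats, ncol, 1L))
  if (length(d) != 1L) stop("inconsistent augmented vector lengths")
  n <- sum(vapply(mats, nrow, 1L))
  if (n < 2L) stop("need at least 2 samples")
  mu <- Reduce(`+`, lapply(mats, colSums)) / n
  C <- matrix(0, d, d)
  for (m in mats) {
    xc <- sweep(m, 2, mu)
    C <- C + crossprod(xc)
  }
  list(C = C / n, mean = mu, n = n)
}

#' Principal-component basis of a covariance matrix
#'
#' Top-`m` eigenpairs with a deterministic sign convention (the largest-
#' magnitude entry of each eigenvector is made positive). `V diag(lambda)
#' V^T` is the best rank-`m` Frobenius approximation of `C`.
#'
#' @param C symmetric positive semidefinite matrix.
#' @param m retained dimension (1 <= m <= ncol(C)).
#' @param rank_tol relative eigenvalue threshold defining the numerical
#'   rank; a warning is emitted when `m` exceeds it.
#' @return list with `V` (d x m, orthonormal columns), `lambda`
#'   (descending, non-negative), `var_retained` (fraction of total variance).
#' @export
pca_basis <- function(C, m, rank_tol = 1e-12) {
  d <- ncol(C)
  stopifnot(m >= 1, m <= d, isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  rank <- sum(lambda > rank_tol * max(lambda, .Machine$double.eps))
  if (m > rank)
    warning(sprintf("retained dimension m = %d exceeds numerical rank %d", m, rank))
  V <- eg$vectors[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  tot <- sum(lambda)
  list(V = V, lambda = lambda[seq_len(m)],
       var_retained = if (tot > 0) sum(lambda[seq_len(m)]) / tot else 1,
       rank = rank)
}

#' Build the latent basis for cells and ECM from training runs
#'
#' Pools augmented samples over runs (and cells within runs), forms the two
#' covariance matrices, and eigendecomposes each. When the pooled sample
#' count is smaller than the augmented dimension the eigenproblem is solved
#' through the thin SVD of the centered data matrix (same eigenvectors,
#' cheaper in the thin-data regime).
#'
#' @param trajs list of `ecm_trajectory` training runs.
#' @param m_c,m_e retained latent dimensions for cell and ECM.
#' @param block_scale scale each augmented block (coordinates, cortical
#'   forces, FA forces; ECM coordinates, elastic forces) to unit pooled
#'   variance before the covariance analysis (default FALSE). Coordinates
#'   (um) and forces (nN) live on incommensurate scales; without balancing,
#'   the eigenbasis resolves geometry well but force blocks poorly, and
#'   force-reconstruction error integrates into spurious net drift during
#'   reduced-order rollouts. The scales are stored with the basis and
#'   inverted on reconstruction, so the transformation is lossless.
#' @return object of class `latent_basis` with fields `Vc`, `Ve`
#'   (orthonormal in the scaled space), block scale vectors `scale_c`,
#'   `scale_e`, `lambda_c`, `lambda_e`, centering means `mean_c`, `mean_e`,
#'   block dimensions, and retained-variance fractions.
#' @export
build_latent_basis <- function(trajs, m_c = 50, m_e = 50, block_scale = FALSE) {
  aug <- lapply(trajs, build_augmented)
  cell_mats <- unlist(lapply(aug, `[[`, "zeta_c"), recursive = FALSE)
  ecm_mats <- lapply(aug, `[[`, "zeta_e")
  n_c <- ncol(cell_mats[[1]]) / 9
  n_e <- ncol(ecm_mats[[1]]) / 6
  if (block_scale) {
    scale_c <- block_scales(cell_mats, rep(1:3, each = 3 * n_c))
    scale_e <- block_scales(ecm_mats, rep(1:2, each = 3 * n_e))
  } else {
    scale_c <- rep(1, 9 * n_c)
    scale_e <- rep(1, 6 * n_e)
  }
  bc <- basis_from_samples(lapply(cell_mats, function(m)
    sweep(m, 2, scale_c, "/")), m_c)
  be <- basis_from_samples(lapply(ecm_mats, function(m)
    sweep(m, 2, scale_e, "/")), m_e)
  ## centering means are stored on the original (unscaled) axis
  structure(list(Vc = bc$V, Ve = be$V, lambda_c = bc$lambda,
                 lambda_e = be$lambda,
                 mean_c = bc$mean * scale_c, mean_e = be$mean * scale_e,
                 scale_c = scale_c, scale_e = scale_e,
                 m_c = ncol(bc$V), m_e = ncol(be$V),
                 n_cell_nodes = n_c, n_ecm_nodes = n_e,
                 var_retained_c = bc$var_retained,
                 var_retained_e = be$var_retained,
                 lambda_full_c = bc$lambda_full, lambda_full_e = be$lambda_full),
            class = "latent_basis")
}

## One pooled standard deviation per block, replicated entrywise.
block_scales <- function(mats, block_id) {
  n <- sum(vapply(mats, nrow, 1L))
  mu <- Reduce(`+`, lapply(mats, colSums)) / n
  ss <- Reduce(`+`, lapply(mats, function(m)
    colSums(sweep(m, 2, mu)^2))) / n
  out <- numeric(length(block_id))
  for (b in unique(block_id)) {
    s <- sqrt(mean(ss[block_id == b]))
    out[block_id == b] <- max(s, 1e-8)
  }
  out
}

basis_from_samples <- function(mats, m) {
  d <- ncol(mats[[1]])
  n <- sum(vapply(mats, nrow, 1L))
  if (n >= d) {
    cov <- augmented_covariance(mats)
    pb <- pca_basis(cov$C, m)
    lambda_full <- eigen((cov$C + t(cov$C)) / 2, symmetric = TRUE,
                         only.values = TRUE)$values
    list(V = pb$V, lambda = pb$lambda, mean = cov$mean,
         var_retained = pb$var_retained, lambda_full = pmax(lambda_full, 0))
  } else {
    X <- do.call(rbind, mats)
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    sv <- svd(Xc, nu = 0)
    lambda_full <- sv$d^2 / n
    m_eff <- min(m, length(lambda_full))
    if (m_eff < m)
      warning("retained dimension reduced to the number of samples")
    V <- sv$v[, seq_len(m_eff), drop = FALSE]
    for (j in seq_len(m_eff)) {
      i <- which.max(abs(V[, j]))
      if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    list(V = V, lambda = lambda_full[seq_len(m_eff)], mean = mu,
         var_retained = sum(lambda_full[seq_len(m_eff)]) / max(sum(lambda_full), .Machine$double.eps),
         lambda_full = lambda_full)
  }
}

#' @export
print.latent_basis <- function(x, ...) {
  cat(sprintf(
    "<latent_basis> cell: 9x%d -> m_c = %d (%.2f%% var); ECM: 6x%d -> m_e = %d (%.2f%% var)\n",
    x$n_cell_nodes, x$m_c, 100 * x$var_retained_c,
    x$n_ecm_nodes, x$m_e, 100 * x$var_retained_e))
  invisible(x)
}

#' Project augmented vectors into latent coordinates
#'
#' `z = V^T (zeta - mean)`; rows are samples.
#'
#' @param zeta matrix (or vector) of augmented samples.
#' @param basis a `latent_basis`.
#' @param entity `"cell"` or `"ecm"`.
#' @return matrix of latent rows (T x m).
#' @export
project_latent <- function(zeta, basis, entity = c("cell", "ecm")) {
  entity <- match.arg(entity)
  if (is.null(dim(zeta))) zeta <- matrix(zeta, nrow = 1)
  V <- if (entity == "cell") basis$Vc else basis$Ve
  mu <- if (entity == "cell") basis$mean_c else basis$mean_e
  s <- basis_scales(basis, entity)
  stopifnot(ncol(zeta) == nrow(V))
  sweep(sweep(zeta, 2, mu), 2, s, "/") %*% V
}

basis_scales <- function(basis, entity) {
  s <- if (entity == "cell") basis$scale_c else basis$scale_e
  if (is.null(s)) {
    d <- if (entity == "cell") 9 * basis$n_cell_nodes else 6 * basis$n_ecm_nodes
    s <- rep(1, d)
  }
  s
}

#' Reconstruct augmented vectors from latent coordinates
#'
#' `zeta_hat = V z + mean`; the reconstruction residual is orthogonal to the
#' basis columns.
#'
#' @param z matrix (or vector) of latent rows.
#' @inheritParams project_latent
#' @return matrix of reconstructed augmented rows.
#' @export
reconstruct_latent <- function(z, basis, entity = c("cell", "ecm")) {
  entity <- match.arg(entity)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  V <- if (entity == "cell") basis$Vc else basis$Ve
  mu <- if (entity == "cell") basis$mean_c else basis$mean_e
  s <- basis_scales(basis, entity)
  stopifnot(ncol(z) == ncol(V))
  sweep(sweep(z %*% t(V), 2, s, "*"), 2, mu, "+")
}

## Named sub-blocks of the basis matrices (x / force rows). `role` selects
## the direction in which the block is used: "rec" rows reconstruct
## physical values (scaled), "proj" rows project physical derivatives into
## latent coordinates (inverse-scaled); they coincide when block scaling is
## off.
basis_block <- function(basis, which, role = c("rec", "proj")) {
  role <- match.arg(role)
  nc3 <- 3 * basis$n_cell_nodes
  ne3 <- 3 * basis$n_ecm_nodes
  idx <- switch(which,
                Vxc = 1:nc3,
                VFCEc = (nc3 + 1):(2 * nc3),
                VFFAc = (2 * nc3 + 1):(3 * nc3),
                Vxe = 1:ne3,
                VFElase = (ne3 + 1):(2 * ne3),
                stop("unknown block"))
  entity <- if (which %in% c("Vxc", "VFCEc", "VFFAc")) "cell" else "ecm"
  V <- if (entity == "cell") basis$Vc else basis$Ve
  s <- basis_scales(basis, entity)[idx]
  blk <- V[idx, , drop = FALSE]
  if (role == "rec") blk * s else blk / s
}
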