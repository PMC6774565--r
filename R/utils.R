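#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix sparseMatrix Diagonal
#' @importFrom stats rnorm runif setNames
#' @importFrom methods as is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Row-wise vector helpers for n x 3 coordinate matrices --------------------

row_norms <- function(m) sqrt(rowSums(m * m))

unitize_rows <- function(m, tol = 1e-12) {
  n <- row_norms(m)
  n[n < tol] <- 1
  m / n
}

#' Row-wise cross product of two n x 3 matrices
#' @keywords internal
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unitize <- function(v, tol = 1e-12) {
  n <- sqrt(sum(v * v))
  if (n < tol) stop("cannot normalize a (near-)zero vector")
  v / n
}

## Coordinate flattening: n x 3 matrix <-> length-3n vector (node-major,
## i.e. (x1,y1,z1,x2,y2,z2,...)), the layout used for all stacked state
## vectors in the package.

flatten_coords <- function(m) as.vector(t(m))

unflatten_coords <- function(v) matrix(v, ncol = 3, byrow = TRUE)

stopifnot_finite <- function(x, what = "coordinates") {
  if (!all(is.finite(x))) stop(sprintf("non-finite %s encountered", what))
}

## Simple BFS connectivity on an undirected edge list ------------------------

graph_connected <- function(n_nodes, edges) {
  if (n_nodes <= 1L) return(TRUE)
  adj <- vector("list", n_nodes)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n_nodes)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

## Accumulate per-element 3-vectors onto nodes -------------------------------

accumulate_rows <- function(n_nodes, idx, vals) {
  out <- matrix(0, n_nodes, 3)
  for (c in 1:3) {
    s <- rowsum(vals[, c], group = idx, reorder = FALSE)
    out[as.integer(rownames(s)), c] <- out[as.integer(rownames(s)), c] + s[, 1]
  }
  out
}
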