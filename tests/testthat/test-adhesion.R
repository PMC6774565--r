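make_bond_state <- function(bonds_df, n_cells = 1, params = default_params()) {
  st <- adhesion_state(n_cells, params)
  if (is.data.frame(bonds_df)) bonds_df <- list(bonds_df)
  for (k in seq_along(bonds_df)) st$bonds[[k]] <- bonds_df[[k]]
  st
}

test_that("no bonds gives all-zero forces and a zero mapping matrix", {
  st <- adhesion_state(1)
  xc <- matrix(rnorm(9), 3)
  xe <- matrix(rnorm(12), 4)
  f <- fa_forces(st, list(xc), xe)
  expect_true(all(f$cell[[1]] == 0) && all(f$ecm == 0))
  P <- build_mapping_matrix(st, 1, 4, 3)
  expect_equal(dim(P), c(12L, 9L))
  expect_equal(length(P@x), 0L)
})

test_that("a single bond produces the paired spring force pair", {
  st <- make_bond_state(data.frame(i = 1L, j = 2L, n_int = 1L),
                        params = default_params(k_FA = 0.5))
  xc <- matrix(c(0, 0, 0), 1, 3)
  xe <- rbind(c(9, 9, 9), c(1, 0, 0))
  f <- fa_forces(st, list(xc), xe)
  expect_equal(f$cell[[1]][1, ], c(0.5, 0, 0))
  expect_equal(f$ecm[2, ], c(-0.5, 0, 0))
  expect_equal(f$ecm[1, ], c(0, 0, 0))
})

test_that("global FA force cancellation holds to machine precision", {
  set.seed(5)
  for (rep in 1:5) {
    n_c <- 6; n_e <- 20
    b1 <- data.frame(i = 1:3, j = sample(n_e, 3), n_int = c(1L, 5L, 10L))
    b2 <- data.frame(i = 2:4, j = sample(setdiff(seq_len(n_e), b1$j), 3),
                     n_int = c(2L, 3L, 7L))
    st <- make_bond_state(list(b1, b2), n_cells = 2)
    xc <- list(matrix(rnorm(3 * n_c), n_c), matrix(rnorm(3 * n_c), n_c))
    xe <- matrix(5 * rnorm(3 * n_e), n_e)
    f <- fa_forces(st, xc, xe)
    tot <- colSums(f$ecm) + colSums(f$cell[[1]]) + colSums(f$cell[[2]])
    expect_lt(max(abs(tot)), 1e-12)
  }
})

test_that("the mapping matrix has the -I3 block structure", {
  st <- make_bond_state(data.frame(i = 2L, j = 5L, n_int = 10L))
  P <- build_mapping_matrix(st, 1, 8, 3)
  expect_equal(length(P@x), 3L)
  expect_true(all(P@x == -1))
  dense <- as.matrix(P)
  expect_equal(dense[13:15, 4:6], -diag(3), ignore_attr = TRUE)
  dense[13:15, 4:6] <- 0
  expect_true(all(dense == 0))
})

test_that("P_map reproduces the assembled ECM FA forces of each cell", {
  set.seed(11)
  n_c <- 5; n_e <- 12
  b1 <- data.frame(i = c(1L, 4L), j = c(3L, 9L), n_int = c(10L, 4L))
  b2 <- data.frame(i = c(2L, 5L), j = c(7L, 1L), n_int = c(1L, 6L))
  st <- make_bond_state(list(b1, b2), n_cells = 2)
  xc <- list(matrix(rnorm(3 * n_c), n_c), matrix(rnorm(3 * n_c), n_c))
  xe <- matrix(rnorm(3 * n_e), n_e)
  f <- fa_forces(st, xc, xe)
  total <- numeric(3 * n_e)
  for (k in 1:2) {
    P <- build_mapping_matrix(st, k, n_e, n_c)
    total <- total + as.vector(P %*% flatten_coords(f$cell[[k]]))
  }
  expect_equal(total, flatten_coords(f$ecm), tolerance = 1e-12)
})

test_that("one ECM node bonded by two cells is rejected", {
  st <- make_bond_state(list(data.frame(i = 1L, j = 3L, n_int = 1L),
                             data.frame(i = 2L, j = 3L, n_int = 1L)),
                        n_cells = 2)
  expect_error(build_mapping_matrix(st, 1, 5, 4), "more than one cell")
})

test_that("attachment and distance-based detachment follow the rules", {
  p <- default_params(d_bind = 1, d_break = 3, p_on = 1)
  st <- adhesion_state(1, p)
  xc <- matrix(c(0, 0, 0), 1, 3)
  xe <- rbind(c(0.5, 0, 0), c(10, 0, 0))
  set.seed(1)
  st2 <- update_adhesions(st, list(xc), xe)
  expect_equal(nrow(st2$bonds[[1]]), 1L)
  expect_equal(st2$bonds[[1]]$j, 1L)
  ## stretch the bond beyond d_break: it detaches
  xe_far <- rbind(c(5, 0, 0), c(10, 0, 0))
  st3 <- update_adhesions(st2, list(xc), xe_far)
  expect_equal(nrow(st3$bonds[[1]]), 0L)
})

test_that("boundary-fixed and occupied ECM nodes are never bound", {
  p <- default_params(d_bind = 2, d_break = 4, p_on = 1)
  st <- adhesion_state(2, p)
  xc1 <- matrix(c(0, 0, 0), 1, 3)
  xc2 <- matrix(c(0.2, 0, 0), 1, 3)
  xe <- rbind(c(0.5, 0, 0), c(100, 0, 0))
  set.seed(1)
  st2 <- update_adhesions(st, list(xc1, xc2), xe,
                          boundary_fixed = c(FALSE, FALSE))
  ## node 1 taken by cell 1; cell 2 finds nothing free in range
  expect_equal(nrow(st2$bonds[[1]]), 1L)
  expect_equal(nrow(st2$bonds[[2]]), 0L)
  st3 <- update_adhesions(st, list(xc1, xc2), xe,
                          boundary_fixed = c(TRUE, TRUE))
  expect_equal(nrow(st3$bonds[[1]]) + nrow(st3$bonds[[2]]), 0L)
})

test_that("bond history is deterministic for a fixed seed", {
  w <- tiny_world()
  cfg <- sim_config(dt = 0.1, t_end = 5, sample_interval = 1, seed = 42)
  t1 <- simulate_full(w, cfg)
  t2 <- simulate_full(w, cfg)
  expect_identical(t1$bonds, t2$bonds)
  expect_identical(t1$xe, t2$xe)
})
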