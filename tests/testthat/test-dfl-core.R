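small_traj <- function(t_end = 10, n_cells = 1, seed = 6) {
  p <- default_params(cell_radius = 4)
  net <- tiny_net(3, p)
  cells <- lapply(seq_len(n_cells), function(k)
    cell_mesh(c(8 + 12 * (k - 1), 0, 0), cell_id = k, params = p))
  w <- sim_world(net, cells, params = p)
  simulate_full(w, sim_config(dt = 0.1, t_end = t_end, sample_interval = 1,
                              seed = seed))
}

test_that("augmented assembly stacks blocks losslessly", {
  tr <- small_traj(5)
  aug <- build_augmented(tr)
  expect_equal(ncol(aug$zeta_c[[1]]), 9 * tr$cells[[1]]$n_nodes)
  expect_equal(ncol(aug$zeta_e), 6 * tr$net$n_nodes)
  sp <- split_augmented(aug$zeta_c[[1]], "cell")
  expect_identical(sp$x, tr$xc[[1]])
  expect_identical(sp$Fce, tr$Fce[[1]])
  expect_identical(sp$Ffa, tr$Ffa[[1]])
  se <- split_augmented(aug$zeta_e, "ecm")
  expect_identical(se$x, tr$xe)
  expect_identical(se$Fe, tr$Fe)
})

test_that("two cells give two cell vectors and one shared ECM vector", {
  tr <- small_traj(3, n_cells = 2)
  aug <- build_augmented(tr)
  expect_length(aug$zeta_c, 2)
  expect_true(is.matrix(aug$zeta_e))
})

test_that("missing force channels are rejected", {
  tr <- small_traj(3)
  tr$Ffa <- NULL
  expect_error(build_augmented(tr), "force channels")
})

test_that("covariance matches the textbook direct-summation oracle", {
  set.seed(7)
  X <- matrix(rnorm(15), 3, 5)
  cov <- augmented_covariance(X)
  mu <- colMeans(X)
  C_oracle <- matrix(0, 5, 5)
  for (i in 1:3) C_oracle <- C_oracle + tcrossprod(X[i, ] - mu)
  expect_equal(cov$C, C_oracle / 3, tolerance = 1e-12)
  ## identical samples give the zero matrix
  same <- matrix(1, 4, 5) * rep(rnorm(5), each = 4)
  expect_lt(max(abs(augmented_covariance(same)$C)), 1e-14)
  ## pooling over a list equals pooling over rbind
  cov2 <- augmented_covariance(list(X[1:2, ], X[3, , drop = FALSE]))
  expect_equal(cov2$C, cov$C, tolerance = 1e-12)
})

test_that("linear-force data has covariance rank equal to excited modes", {
  ## exactly linear augmented samples: zeta = (x; K x), x excited along
  ## r directions only -> rank r regardless of the force block
  set.seed(8)
  d <- 6
  K <- crossprod(matrix(rnorm(d * d), d))
  for (r in c(1, 2, 4)) {
    basis_dirs <- qr.Q(qr(matrix(rnorm(d * r), d)))
    coeffs <- matrix(rnorm(40 * r), 40)
    X <- coeffs %*% t(basis_dirs)
    Z <- cbind(X, X %*% K)
    C <- augmented_covariance(Z)$C
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev > 1e-10 * max(ev)), r)
  }
})

test_that("pca_basis handles identity, diagonal and random PSD cases", {
  b <- pca_basis(diag(3), 3)
  expect_equal(b$lambda, rep(1, 3))
  expect_equal(crossprod(b$V), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  b2 <- pca_basis(diag(c(4, 1, 0)), 1)
  expect_equal(b2$lambda, 4)
  expect_equal(abs(b2$V[, 1]), c(1, 0, 0), tolerance = 1e-12)
  set.seed(10)
  C <- crossprod(matrix(rnorm(400), 20))
  b3 <- pca_basis(C, 5)
  eg <- eigen(C, symmetric = TRUE)
  expect_equal(b3$lambda, eg$values[1:5], tolerance = 1e-10)
  expect_equal(b3$var_retained, sum(eg$values[1:5]) / sum(eg$values),
               tolerance = 1e-10)
  ## best rank-m approximation property (Frobenius)
  approx <- b3$V %*% diag(b3$lambda) %*% t(b3$V)
  expect_equal(norm(C - approx, "F"), sqrt(sum(eg$values[6:20]^2)),
               tolerance = 1e-8)
  expect_warning(pca_basis(diag(c(1, 0, 0)), 3), "rank")
})

test_that("retained variance is monotone non-decreasing in m", {
  set.seed(3)
  C <- crossprod(matrix(rnorm(100), 10))
  vr <- sapply(1:10, function(m) pca_basis(C, m)$var_retained)
  expect_true(all(diff(vr) >= -1e-12))
})

test_that("projection and reconstruction are consistent", {
  tr <- small_traj(8)
  basis <- suppressWarnings(build_latent_basis(list(tr), m_c = 20, m_e = 20))
  aug <- build_augmented(tr)
  z <- project_latent(aug$zeta_c[[1]], basis, "cell")
  zeta_hat <- reconstruct_latent(z, basis, "cell")
  resid <- aug$zeta_c[[1]] - zeta_hat
  ## residual orthogonal to the basis columns
  expect_lt(max(abs(sweep(resid, 2, 0) %*% basis$Vc)), 1e-8)
  ## z = 0 reconstructs the stored mean
  expect_equal(as.vector(reconstruct_latent(rep(0, basis$m_c), basis, "cell")),
               basis$mean_c, tolerance = 1e-12)
  ## a vector already in the reconstruction span round-trips exactly
  v <- as.vector(reconstruct_latent(rnorm(basis$m_c), basis, "cell"))
  expect_equal(as.vector(reconstruct_latent(
    project_latent(v, basis, "cell"), basis, "cell")), v, tolerance = 1e-10)
})

test_that("a full-rank basis reconstructs the training set to numerical zero", {
  tr <- small_traj(8)
  aug <- build_augmented(tr)
  n_samp <- nrow(aug$zeta_c[[1]])
  ## thin-data regime: rank limited by samples; keep every available mode
  basis <- build_latent_basis(list(tr), m_c = min(n_samp, 9 * tr$cells[[1]]$n_nodes),
                              m_e = min(n_samp, 6 * tr$net$n_nodes))
  z <- project_latent(aug$zeta_c[[1]], basis, "cell")
  err <- aug$zeta_c[[1]] - reconstruct_latent(z, basis, "cell")
  expect_lt(sqrt(mean(err^2)), 1e-8)
})
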