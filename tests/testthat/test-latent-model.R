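## Planted-model data: draw latent samples and compute exact derivatives
## from known (A, B, C, G); the estimator must recover them.
planted_data <- function(m_c = 10, m_e = 10, n_u = 6, n = 400, seed = 1) {
  set.seed(seed)
  stabilize <- function(M) M - diag(nrow(M)) * (max(Re(eigen(M)$values)) + 0.5)
  A <- stabilize(matrix(rnorm(m_c^2), m_c) / sqrt(m_c))
  G <- stabilize(matrix(rnorm(m_e^2), m_e) / sqrt(m_e))
  B <- matrix(rnorm(m_c * n_u), m_c) / sqrt(n_u)
  C <- matrix(rnorm(m_c * m_e), m_c) / sqrt(m_e)
  zc <- matrix(rnorm(n * m_c), n)
  ze <- matrix(rnorm(n * m_e), n)
  u <- matrix(rnorm(n * n_u), n)
  inj <- matrix(rnorm(n * m_e), n)
  dzc <- zc %*% t(A) + u %*% t(B) + ze %*% t(C)
  dze <- ze %*% t(G) + inj
  list(ld = list(zc = zc, u = u, ze = ze, dzc = dzc, dze = dze,
                 fa_inj = inj, m_c = m_c, m_e = m_e),
       A = A, B = B, C = C, G = G)
}

test_that("planted stable linear latent dynamics are recovered entrywise", {
  pd <- planted_data()
  m <- estimate_parameters(pd$ld, basis = NULL, lambda = 0)
  expect_lt(max(abs(m$A - pd$A)), 1e-6)
  expect_lt(max(abs(m$B - pd$B)), 1e-6)
  expect_lt(max(abs(m$C - pd$C)), 1e-6)
  expect_lt(max(abs(m$G - pd$G)), 1e-6)
  expect_lt(max(abs(c(m$a0, m$g0))), 1e-6)
  expect_lt(max(m$spectral_abscissa), 0)
})

test_that("estimates are invariant to sample duplication", {
  pd <- planted_data(m_c = 4, m_e = 4, n_u = 2, n = 60)
  dup <- lapply(pd$ld[c("zc", "u", "ze", "dzc", "dze", "fa_inj")],
                function(m) rbind(m, m))
  dup$m_c <- 4; dup$m_e <- 4
  m1 <- estimate_parameters(pd$ld, NULL, lambda = 0)
  m2 <- estimate_parameters(dup, NULL, lambda = 0)
  expect_equal(m1$A, m2$A, tolerance = 1e-9)
  expect_equal(m1$G, m2$G, tolerance = 1e-9)
})

test_that("unexcited inputs warn and are ridged toward zero", {
  pd <- planted_data(m_c = 4, m_e = 4, n_u = 3, n = 100, seed = 2)
  pd$ld$u[] <- 0
  pd$ld$dzc <- pd$ld$zc %*% t(pd$A) + pd$ld$ze %*% t(pd$C)
  expect_warning(m <- estimate_parameters(pd$ld, NULL, lambda = 1e-6),
                 "identically zero")
  expect_lt(max(abs(m$B)), 1e-6)
  expect_error(suppressWarnings(estimate_parameters(pd$ld, NULL, lambda = 0)),
               "rank")
})

test_that("D^k assembly matches the matrix-free injection exactly", {
  ## identity-like full-rank bases on a tiny world
  n_c <- 3; n_e <- 5
  basis <- structure(list(
    Vc = diag(9 * n_c), Ve = diag(6 * n_e),
    mean_c = rnorm(9 * n_c), mean_e = rep(0, 6 * n_e),
    m_c = 9 * n_c, m_e = 6 * n_e,
    n_cell_nodes = n_c, n_ecm_nodes = n_e), class = "latent_basis")
  st <- adhesion_state(1)
  st$bonds[[1]] <- data.frame(i = c(1L, 3L), j = c(2L, 5L), n_int = c(10L, 5L))
  P <- build_mapping_matrix(st, 1, n_e, n_c)
  D_e <- 7
  dk <- assemble_Dk(P, basis, D_e)
  expect_equal(dim(dk$Dk), c(6 * n_e, 9 * n_c))
  set.seed(3)
  zc <- rnorm(9 * n_c)
  ## matrix-free route
  VFFAc <- basis$Vc[(6 * n_c + 1):(9 * n_c), , drop = FALSE]
  mu_ffa <- basis$mean_c[(6 * n_c + 1):(9 * n_c)]
  fhat <- as.vector(VFFAc %*% zc) + mu_ffa
  inj <- ecmsuper:::fa_injection_latent(st$bonds, list(fhat),
                                        basis$Ve[1:(3 * n_e), ], D_e)
  expect_equal(inj, as.vector(dk$Dk %*% zc) + dk$d0, tolerance = 1e-12)
  ## no bonds -> zero coupling
  st0 <- adhesion_state(1)
  P0 <- build_mapping_matrix(st0, 1, n_e, n_c)
  dk0 <- assemble_Dk(P0, basis, D_e)
  expect_true(all(dk0$Dk == 0) && all(dk0$d0 == 0))
})

test_that("adding one bond changes D^k by a rank <= 3 update", {
  n_c <- 4; n_e <- 6
  basis <- structure(list(
    Vc = diag(9 * n_c), Ve = diag(6 * n_e),
    mean_c = rep(0, 9 * n_c), mean_e = rep(0, 6 * n_e),
    m_c = 9 * n_c, m_e = 6 * n_e,
    n_cell_nodes = n_c, n_ecm_nodes = n_e), class = "latent_basis")
  st1 <- adhesion_state(1)
  st1$bonds[[1]] <- data.frame(i = 1L, j = 2L, n_int = 10L)
  st2 <- st1
  st2$bonds[[1]] <- rbind(st1$bonds[[1]],
                          data.frame(i = 3L, j = 4L, n_int = 10L))
  d1 <- assemble_Dk(build_mapping_matrix(st1, 1, n_e, n_c), basis, 1)
  d2 <- assemble_Dk(build_mapping_matrix(st2, 1, n_e, n_c), basis, 1)
  expect_lte(qr(d2$Dk - d1$Dk)$rank, 3L)
})

test_that("zero initial latent state with u = 0 and stable G stays at zero", {
  ## a stress-free world (zero cortical tension, no bonds) whose augmented
  ## state equals the basis centering mean projects to exactly zero latent
  w <- tiny_world(f_L = 0, gamma = 0)
  tr <- simulate_full(w, sim_config(dt = 0.1, t_end = 5, sample_interval = 1,
                                    seed = 2, update_adhesions = FALSE,
                                    update_polarity = FALSE))
  basis <- build_latent_basis(list(tr), m_c = 4, m_e = 4)
  basis$mean_c <- c(flatten_coords(w$xc[[1]]),
                    rep(0, 6 * w$cells[[1]]$n_nodes))
  basis$mean_e <- c(flatten_coords(w$xe), rep(0, 3 * w$net$n_nodes))
  model <- structure(list(
    A = -diag(4), B = matrix(0, 4, 3 * w$cells[[1]]$n_nodes),
    C = matrix(0, 4, 4), G = -diag(4), a0 = rep(0, 4), g0 = rep(0, 4),
    basis = basis, D_e = w$net$D_e, lambda = 0), class = "latent_model")
  cfg <- sim_config(dt = 0.1, t_end = 5, sample_interval = 1, seed = 1,
                    update_adhesions = FALSE, update_polarity = FALSE)
  lt <- simulate_latent(model, w, cfg)
  expect_lt(max(abs(lt$ze)), 1e-10)
  expect_lt(max(abs(lt$zc[[1]])), 1e-10)
  ## reconstructed geometry stays pinned at the equilibrium
  expect_equal(lt$xe[nrow(lt$xe), ], flatten_coords(w$xe), tolerance = 1e-10)
})
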