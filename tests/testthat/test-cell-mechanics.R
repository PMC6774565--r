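test_that("the membrane mesh is a closed 2-manifold", {
  cl <- cell_mesh(c(1, 2, 3))
  expect_equal(cl$n_nodes, 42L)
  expect_equal(nrow(cl$triangles), 80L)
  ## Euler characteristic V - E + F = 2 for a sphere
  expect_equal(cl$n_nodes - nrow(cl$edges) + nrow(cl$triangles), 2L)
  ## every edge shared by exactly two triangles
  tri <- cl$triangles
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))
})

test_that("rest configuration is force free when cortical tension is off", {
  cl <- cell_mesh(c(0, 0, 0), params = default_params(gamma = 0))
  f <- cortical_elastic_forces(cl, cl$nodes)
  expect_lt(max(abs(f)), 1e-12)
})

test_that("cortical forces equal minus the energy gradient and sum to zero", {
  cl <- cell_mesh(c(0, 0, 0))
  set.seed(4)
  x <- cl$nodes * 1.05 + 0.05 * matrix(rnorm(3 * cl$n_nodes), ncol = 3)
  f <- flatten_coords(cortical_elastic_forces(cl, x))
  g <- num_grad(function(v) cortical_energy(cl, unflatten_coords(v)),
                flatten_coords(x))
  expect_lt(max(abs(f + g)) / max(abs(g)), 1e-5)
  expect_lt(max(abs(colSums(cortical_elastic_forces(cl, x)))), 1e-9)
})

test_that("a uniformly inflated membrane is pulled inward everywhere", {
  cl <- cell_mesh(c(0, 0, 0))
  f <- cortical_elastic_forces(cl, cl$nodes * 1.1)
  radial <- rowSums(f * unitize_rows(cl$nodes))
  expect_true(all(radial < 0))
})

test_that("polarity has the aligned and anti-aligned fixed points", {
  p <- polarity_state(c(1, 0, 0), params = default_params(kappa = 0.5))
  expect_equal(update_polarity(p, c(1, 0, 0), 0.1)$d_pol, c(1, 0, 0))
  expect_equal(update_polarity(p, c(-1, 0, 0), 0.1)$d_pol, c(1, 0, 0))
})

test_that("perpendicular polarity rotates at rate kappa sin(theta)", {
  p <- polarity_state(c(1, 0, 0), params = default_params(kappa = 1))
  p2 <- update_polarity(p, c(0, 0, 1), 0.01)   # kappa dt = 0.01, theta = pi/2
  ang0 <- acos(sum(p$d_pol * c(0, 0, 1)))
  ang1 <- acos(sum(p2$d_pol * c(0, 0, 1)))
  expect_equal(ang0 - ang1, 0.01, tolerance = 1e-4)
  ## rotation stays in the plane spanned by the two directions
  expect_lt(abs(p2$d_pol[2]), 1e-12)
})

test_that("polarity norm is preserved over 1e4 steps", {
  p <- polarity_state(unitize(c(1, 2, -1)), params = default_params(kappa = 0.01))
  target <- unitize(c(-1, 0.5, 2))
  for (i in 1:10000) p <- update_polarity(p, target, 0.1)
  expect_equal(sqrt(sum(p$d_pol^2)), 1, tolerance = 1e-6)
  ## and it has converged to the target
  expect_gt(sum(p$d_pol * target), 1 - 1e-6)
})

test_that("lamellipodial support is exactly the cone-membership set", {
  cl <- cell_mesh(c(0, 0, 0))
  prm <- default_params(f_L = 2)
  for (alpha in c(pi / 6, pi / 4, 1.2)) {
    prm$alpha_L <- alpha
    p <- polarity_state(c(0, 0, 1), params = prm)
    u <- matrix(lamellipodial_input(cl, cl$nodes, p), ncol = 3, byrow = TRUE)
    dirs <- unitize_rows(sweep(cl$nodes, 2, colMeans(cl$nodes)))
    in_cone <- as.vector(dirs %*% c(0, 0, 1)) >= cos(alpha)
    loaded <- rowSums(abs(u)) > 0
    expect_identical(loaded, in_cone)
    expect_equal(row_norms(u[loaded, , drop = FALSE]),
                 rep(2, sum(loaded)), tolerance = 1e-12)
  }
})

test_that("degenerate cone angles load everything or almost nothing", {
  cl <- cell_mesh(c(0, 0, 0))
  p_all <- polarity_state(c(1, 0, 0), params = default_params(alpha_L = pi))
  u <- matrix(lamellipodial_input(cl, cl$nodes, p_all), ncol = 3, byrow = TRUE)
  expect_true(all(rowSums(abs(u)) > 0))
  p_none <- polarity_state(unitize(c(1, 0.3, 0.2)),
                           params = default_params(alpha_L = 1e-9))
  u2 <- matrix(lamellipodial_input(cl, cl$nodes, p_none), ncol = 3, byrow = TRUE)
  expect_lte(sum(rowSums(abs(u2)) > 0), 1)
})

test_that("max-stiffness direction follows the fiber tension tensor", {
  ## single taut segment along x
  net <- single_fiber_network(c(-1, 0, 0), c(1, 0, 0), 1)
  x_taut <- rbind(c(-1.3, 0, 0), c(1.3, 0, 0))
  v <- max_stiffness_direction(net, x_taut, c(0, 0, 0), 5)
  expect_equal(abs(v), c(1, 0, 0), tolerance = 1e-12)
  ## all slack: falls back to the current polarity
  v0 <- max_stiffness_direction(net, net$nodes, c(0, 0, 0), 5,
                                current = c(0, 1, 0))
  expect_equal(v0, c(0, 1, 0))
  ## out of range errors
  expect_error(max_stiffness_direction(net, net$nodes, c(100, 0, 0), 5),
               "sensing radius")
})

test_that("two orthogonal segments with 2:1 tension pick the stronger axis", {
  p <- default_params(k_bend = 0)
  nodes <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0))
  net <- ecm_network(nodes, rbind(c(1, 2), c(3, 4)), params = p)
  ## stretch x-segment by 2 delta, y-segment by delta
  x <- rbind(c(-1.2, 0, 0), c(1.2, 0, 0), c(0, -1.1, 0), c(0, 1.1, 0))
  M_oracle <- 0.4 * outer(c(1, 0, 0), c(1, 0, 0)) +
    0.2 * outer(c(0, 1, 0), c(0, 1, 0))
  v_oracle <- eigen(M_oracle, symmetric = TRUE)$vectors[, 1]
  v <- max_stiffness_direction(net, x, c(0, 0, 0), 5)
  expect_equal(abs(sum(v * v_oracle)), 1, tolerance = 1e-10)
})
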