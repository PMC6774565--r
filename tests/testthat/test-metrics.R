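test_that("convex hull volume matches closed-form solids", {
  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  expect_equal(convex_hull_volume(cube), 1, tolerance = 1e-9)
  ## interior points do not change the hull
  set.seed(2)
  inner <- matrix(runif(30, 0.2, 0.8), ncol = 3)
  expect_equal(convex_hull_volume(rbind(cube, inner)), 1, tolerance = 1e-9)
  ## a scaled cloud scales as the cube of the factor
  set.seed(3)
  cloud <- matrix(rnorm(90), ncol = 3)
  v1 <- convex_hull_volume(cloud)
  v2 <- convex_hull_volume(0.9 * cloud)
  expect_equal(v2 / v1, 0.9^3, tolerance = 1e-8)
  ## degenerate clouds have zero volume
  flat <- cbind(runif(10), runif(10), 0)
  expect_equal(convex_hull_volume(flat), 0)
  expect_equal(convex_hull_volume(cube[1:3, ]), 0)
  ## tetrahedron
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(convex_hull_volume(tet), 1 / 6, tolerance = 1e-12)
})

test_that("trajectory RMSE has the closed-form basic cases", {
  w <- tiny_world()
  cfg <- sim_config(dt = 0.1, t_end = 3, sample_interval = 1, seed = 1)
  tr <- simulate_full(w, cfg)
  expect_equal(trajectory_rmse(tr, tr), 0)
  shifted <- tr
  xcols <- function(m) seq(1, ncol(m), by = 3)
  shifted$xe[, xcols(tr$xe)] <- shifted$xe[, xcols(tr$xe)] + 1
  shifted$xc <- lapply(tr$xc, function(m) {
    m[, xcols(m)] <- m[, xcols(m)] + 1
    m
  })
  expect_equal(trajectory_rmse(shifted, tr, "ecm"), 1, tolerance = 1e-12)
  expect_equal(trajectory_rmse(shifted, tr, "cells"), 1, tolerance = 1e-12)
  expect_equal(trajectory_rmse(shifted, tr, "all"), 1, tolerance = 1e-12)
  bad <- tr
  bad$times <- tr$times + 1
  expect_error(trajectory_rmse(bad, tr), "mismatch")
})

test_that("RMSE of gaussian perturbations converges to sigma-like scale", {
  set.seed(9)
  w <- tiny_world()
  cfg <- sim_config(dt = 0.1, t_end = 2, sample_interval = 1, seed = 1)
  tr <- simulate_full(w, cfg)
  sigma <- 0.5
  pert <- tr
  pert$xe <- tr$xe + matrix(rnorm(length(tr$xe), sd = sigma), nrow(tr$xe))
  ## per-node squared distance ~ 3 sigma^2 -> RMSE ~ sigma sqrt(3)
  expect_equal(trajectory_rmse(pert, tr, "ecm"), sigma * sqrt(3),
               tolerance = 0.1)
})

test_that("compaction profile is exactly 1 for an undeformed trajectory", {
  dom <- cylinder_domain(10, 30, 2)
  net <- generate_network(dom, 40, 3, 1.5, seed = 4)
  w <- sim_world(net)
  tr <- simulate_full(w, sim_config(dt = 0.1, t_end = 3, sample_interval = 1,
                                    seed = 1))
  prof <- compaction_profile(tr, 10)
  expect_true(all(abs(prof$profile$norm_volume - 1) < 1e-9))
  expect_equal(total_shrinkage(prof), 0, tolerance = 1e-12)
})

test_that("a uniform 10% radial shrink compacts every slice by ~0.81", {
  dom <- cylinder_domain(10, 30, 2)
  net <- generate_network(dom, 40, 3, 1.5, seed = 4)
  w <- sim_world(net)
  tr <- simulate_full(w, sim_config(dt = 0.1, t_end = 1, sample_interval = 1,
                                    seed = 1))
  x0 <- unflatten_coords(tr$xe[1, ])
  shrunk <- x0
  shrunk[, 2:3] <- 0.9 * shrunk[, 2:3]
  tr$xe[2, ] <- flatten_coords(shrunk)
  prof <- compaction_profile(tr, 10, times = c(0, 1))
  p1 <- prof$profile[prof$profile$time == 1, ]
  expect_equal(p1$norm_volume, rep(0.81, nrow(p1)), tolerance = 1e-6)
})

test_that("inter-cell elastic force metric has the stated basic cases", {
  net <- single_fiber_network(c(0, 0, 0), c(10, 0, 0), 2,
                              params = default_params(k_bend = 0))
  w <- sim_world(net)
  tr <- simulate_full(w, sim_config(dt = 0.1, t_end = 1, sample_interval = 1,
                                    seed = 1))
  f0 <- intercell_elastic_force(tr, c(0, 10))
  expect_true(all(f0$mean_force == 0))
  ## stretch the middle node: two segments loaded
  x <- net$nodes
  x[2, 1] <- 6
  tr$xe[2, ] <- flatten_coords(x)
  tr$Fe[2, ] <- flatten_coords(ecm_elastic_forces(net, x))
  f1 <- intercell_elastic_force(tr, c(0, 10))
  fmag <- row_norms(ecm_elastic_forces(net, x))
  expect_equal(f1$mean_force[2], mean(fmag), tolerance = 1e-12)
  expect_error(intercell_elastic_force(tr, c(100, 110)), "no ECM node")
})

test_that("max edge displacement is zero for frozen frames and tracks moves", {
  net <- tiny_net()
  w <- sim_world(net)
  tr <- simulate_full(w, sim_config(dt = 0.1, t_end = 2, sample_interval = 1,
                                    seed = 1))
  md <- max_edge_displacement(tr, seq_len(net$n_nodes))
  expect_true(all(md$max_disp == 0))
  x <- unflatten_coords(tr$xe[3, ])
  x[5, ] <- x[5, ] + c(0, 2, 0)
  tr$xe[3, ] <- flatten_coords(x)
  md2 <- max_edge_displacement(tr, seq_len(net$n_nodes))
  expect_equal(md2$max_disp[3], 2, tolerance = 1e-12)
})
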