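test_that("a rest-state world does not move", {
  net <- tiny_net()
  w <- sim_world(net)
  cfg <- sim_config(dt = 0.1, t_end = 5, sample_interval = 1, seed = 1)
  tr <- simulate_full(w, cfg)
  for (t in seq_along(tr$times))
    expect_equal(tr$xe[t, ], tr$xe[1, ], tolerance = 1e-14)
})

test_that("overdamped kinematics: displacement is dt * F / D per step", {
  net <- two_node_spring(k = 2, D = 10)
  w <- sim_world(net)
  w$xe[2, ] <- c(1.5, 0, 0)          # stretch 0.5 -> force 1.0 nN toward node 1
  w2 <- step_world(w, dt = 0.1)
  expect_equal(w2$xe[2, 1], 1.5 - 0.1 * (2 * 0.5) / 10, tolerance = 1e-12)
  expect_equal(w2$xe[1, ], c(0, 0, 0))   # clamped end never moves
})

test_that("Euler converges at first order to the exponential relaxation", {
  D <- 10; k <- 1
  net <- two_node_spring(k = k, D = D)
  exact <- function(t) 1 + 0.5 * exp(-k * t / D)   # x(0) = 1.5, rest 1
  errs <- sapply(c(0.2, 0.1, 0.05), function(dt) {
    w <- sim_world(net)
    w$xe[2, ] <- c(1.5, 0, 0)
    n <- round(10 / dt)
    for (s in seq_len(n)) w <- step_world(w, dt)
    abs(w$xe[2, 1] - exact(10))
  })
  expect_lt(errs[3], errs[1])
  ## halving dt roughly halves the error (order 1)
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.35)
  expect_equal(errs[2] / errs[3], 2, tolerance = 0.35)
})

test_that("pure dissipation: total potential energy is non-increasing", {
  w <- tiny_world(f_L = 0)
  ## seed bonds once, then freeze the bond set and polarity loop
  cfg0 <- sim_config(dt = 0.1, t_end = 1, sample_interval = 1, seed = 3)
  set.seed(3)
  w$adhesion <- update_adhesions(w$adhesion, w$xc, w$xe, w$net$boundary_fixed)
  ## perturb the ECM so there is stored energy to dissipate
  set.seed(4)
  free <- !w$net$boundary_fixed
  w$xe[free, ] <- w$xe[free, ] + 0.2 * matrix(rnorm(3 * sum(free)), ncol = 3)
  cfg <- sim_config(dt = 0.1, t_end = 30, sample_interval = 1, seed = 3,
                    update_adhesions = FALSE, update_polarity = FALSE)
  tr <- simulate_full(w, cfg)
  e <- numeric(length(tr$times))
  for (t in seq_along(tr$times)) {
    wt <- w
    wt$xe <- unflatten_coords(tr$xe[t, ])
    wt$xc <- list(unflatten_coords(tr$xc[[1]][t, ]))
    e[t] <- world_energy(wt)
  }
  expect_true(all(diff(e) <= 1e-8))
})

list_to_adhesion <- function(tr, t) {
  st <- adhesion_state(length(tr$cells))
  st$bonds <- tr$bonds[[t]]
  st
}

test_that("recorded forces satisfy the overdamped force balance", {
  w <- tiny_world()
  cfg <- sim_config(dt = 0.1, t_end = 10, sample_interval = 0.1, seed = 5)
  tr <- simulate_full(w, cfg)
  ## at the recorded sampling resolution (= dt) the finite-difference
  ## velocity equals (F_total / D) evaluated at the frame start
  free <- rep(!w$net$boundary_fixed, each = 3)
  for (t in c(1, 11, 51)) {
    fa <- fa_forces(list_to_adhesion(tr, t), list(unflatten_coords(tr$xc[[1]][t, ])),
                    unflatten_coords(tr$xe[t, ]))
    ftot <- tr$Fe[t, ] + flatten_coords(fa$ecm)
    v_fd <- (tr$xe[t + 1, ] - tr$xe[t, ]) / 0.1
    expect_equal(v_fd[free], (ftot / w$net$D_e)[free], tolerance = 1e-8)
  }
})

test_that("simulation halts with a frame index on numerical blow-up", {
  net <- two_node_spring(k = 1e6, D = 1)   # rate 1e6/s >> 2/dt
  w <- sim_world(net)
  w$xe[2, ] <- c(1.5, 0, 0)
  cfg <- sim_config(dt = 0.1, t_end = 10, sample_interval = 1, seed = 1)
  expect_error(simulate_full(w, cfg), "step")
})

test_that("a cell with adhesions compacts nearby ECM over time", {
  w <- tiny_world()
  cfg <- sim_config(dt = 0.1, t_end = 120, sample_interval = 1, seed = 8)
  tr <- simulate_full(w, cfg)
  expect_gt(nrow(tr$bonds[[length(tr$bonds)]][[1]]), 2)
  ## membrane contracts below rest area
  a_end <- membrane_area(w$cells[[1]],
                         unflatten_coords(tr$xc[[1]][nrow(tr$xc[[1]]), ]))
  expect_lt(a_end, w$cells[[1]]$rest_area)
  ## ECM nodes have been displaced
  expect_gt(max(abs(tr$xe[nrow(tr$xe), ] - tr$xe[1, ])), 0.2)
})
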