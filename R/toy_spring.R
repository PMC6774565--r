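## Scalar hard-spring worked example of the augmented-state (dual-faceted)
## linearization idea: a massless spring-damper F - D dx/dt = 0 with the
## hard-spring law F = a x + b x^3. Written in the state variable x the
## dynamics are nonlinear; written in the augmented pair (x, F) the state
## equation dx/dt = F/D is exactly linear and only the force transition
## dF/dt needs a fitted linear regression dF/dt ~ S_x x + S_F F.

#' Define a scalar hard-spring/damper system
#'
#' Spring force `F(x) = a x + b x^3` driving a damper `D` through
#' `F - D dx/dt = 0`, i.e. `dx/dt = (a x + b x^3)/D`. With `b = 0` the
#' system is exactly linear and the state facet `dx/dt = (a/D) x` and force
#' facet `dF/dt = (a/D) F` carry identical information; with `b > 0` the two
#' facets differ and the force facet supplies genuinely new information.
#'
#' @param a linear stiffness (> 0).
#' @param b cubic (hardening) coefficient (>= 0).
#' @param D damping constant (> 0).
#' @return object of class `toy_spring` with `W_F = 1/D`.
#' @export
toy_spring_system <- function(a = 1, b = 1, D = 1) {
  stopifnot(D > 0)
  structure(list(a = a, b = b, D = D, W_F = 1 / D), class = "toy_spring")
}

toy_force <- function(sys, x) sys$a * x + sys$b * x^3

#' Simulate the toy system exactly (RK4) or with explicit Euler
#'
#' @param sys a `toy_spring_system()`.
#' @param x0 initial displacement.
#' @param t_end horizon.
#' @param dt step.
#' @param method `"rk4"` (reference oracle) or `"euler"`.
#' @return data.frame with columns `t`, `x`, `F`.
#' @export
simulate_toy <- function(sys, x0, t_end = 1, dt = 1e-3,
                         method = c("rk4", "euler")) {
  method <- match.arg(method)
  n <- round(t_end / dt)
  x <- numeric(n + 1)
  x[1] <- x0
  rhs <- function(x) toy_force(sys, x) / sys$D
  for (s in seq_len(n)) {
    if (method == "euler") {
      x[s + 1] <- x[s] + dt * rhs(x[s])
    } else {
      k1 <- rhs(x[s])
      k2 <- rhs(x[s] + dt / 2 * k1)
      k3 <- rhs(x[s] + dt / 2 * k2)
      k4 <- rhs(x[s] + dt * k3)
      x[s + 1] <- x[s] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  data.frame(t = dt * (0:n), x = x, F = toy_force(sys, x))
}

#' Fit the force-facet regression dF/dt ~ S_x x + S_F F
#'
#' Least squares over a sampled trajectory of `(x, F)`; derivatives of `F`
#' are forward differences at the sampling interval (the exact adjoint of
#' the explicit Euler companion integrator, so a linear spring is
#' reproduced to numerical precision).
#'
#' @param sys a `toy_spring_system()`.
#' @param traj data.frame from [simulate_toy()].
#' @return list with `S_x`, `S_F` and the residual RMS of the fit.
#' @export
toy_df_fit <- function(sys, traj) {
  n <- nrow(traj)
  if (n < 3) stop("trajectory too short for regression")
  if (!all(is.finite(traj$x)) || !all(is.finite(traj$F)))
    stop("non-finite trajectory (hard-spring growth escapes in finite time; shorten the horizon)")
  if (max(abs(diff(traj$x))) < 1e-14 && max(abs(diff(traj$F))) < 1e-14)
    stop("degenerate regression: constant trajectory carries no dynamics")
  dt <- diff(traj$t[1:2])
  dF <- diff(traj$F) / dt
  X <- cbind(x = traj$x[-n], F = traj$F[-n])
  if (qr(X)$rank < 2) {
    ## exactly linear spring: x and F are collinear and the force facet
    ## alone determines the dynamics (S_x = 0, S_F = a/D)
    S_F <- sum(X[, 2] * dF) / sum(X[, 2]^2)
    beta <- c(0, S_F)
  } else {
    beta <- qr.solve(X, dF)
  }
  list(S_x = unname(beta[1]), S_F = unname(beta[2]),
       residual_rms = sqrt(mean((dF - X %*% beta)^2)))
}

#' Simulate the augmented-linear (dual-facet) toy model
#'
#' Integrates the exactly linear state facet `dx/dt = W_F F` together with
#' the fitted force facet `dF/dt = S_x x + S_F F` (explicit Euler at the
#' training sampling interval).
#'
#' @param sys a `toy_spring_system()`.
#' @param fit output of [toy_df_fit()].
#' @param x0 initial displacement (initial force is `F(x0)` exactly).
#' @param t_end,dt horizon and step.
#' @return data.frame with `t`, `x`, `F`.
#' @export
simulate_toy_df <- function(sys, fit, x0, t_end = 1, dt = 1e-3) {
  n <- round(t_end / dt)
  x <- numeric(n + 1); f <- numeric(n + 1)
  x[1] <- x0; f[1] <- toy_force(sys, x0)
  for (s in seq_len(n)) {
    x[s + 1] <- x[s] + dt * sys$W_F * f[s]
    f[s + 1] <- f[s] + dt * (fit$S_x * x[s] + fit$S_F * f[s])
  }
  data.frame(t = dt * (0:n), x = x, F = f)
}

#' Simulate the first-order Taylor baseline of the toy system
#'
#' Algebraic linearization about `x_ref`:
#' `F(x) ~ F(x_ref) + F'(x_ref) (x - x_ref)`.
#'
#' @param sys a `toy_spring_system()`.
#' @param x0 initial displacement.
#' @param x_ref expansion point (default `x0`).
#' @param t_end,dt horizon and step.
#' @return data.frame with `t`, `x`.
#' @export
simulate_toy_taylor <- function(sys, x0, x_ref = x0, t_end = 1, dt = 1e-3) {
  n <- round(t_end / dt)
  f0 <- toy_force(sys, x_ref)
  j <- sys$a + 3 * sys$b * x_ref^2
  x <- numeric(n + 1); x[1] <- x0
  for (s in seq_len(n))
    x[s + 1] <- x[s] + dt * (f0 + j * (x[s] - x_ref)) / sys$D
  data.frame(t = dt * (0:n), x = x)
}
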