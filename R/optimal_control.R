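#' Controlled model vector field
#'
#' The model with the GDP-funded mitigation effort `u(t)` replacing the
#' constant abatement rate: `dC/dt` gains `(beta - u)G` in place of
#' `(beta - epsilon)G`, and `dG/dt = mu - u G`. A constant
#' `u = epsilon` recovers [model_rhs()] exactly.
#'
#' @param state state `(C, G, F, N)`.
#' @param u control value, `0 <= u`.
#' @param params a [carbo_params()] set.
#' @return Named derivative vector per year.
#' @export
controlled_rhs <- function(state, u, params) {
  if (!is.finite(u) || u < 0) stop("control u must be finite and >= 0",
                                   call. = FALSE)
  x <- as_state(state)
  p <- as_carbo_params(params)
  C <- x[[1]]; G <- x[[2]]; Fa <- x[[3]]; N <- x[[4]]
  c(C = p[["alpha"]] + p[["phi"]] * N + (p[["beta"]] - u) * G -
        p[["eta"]] * C * Fa - p[["p"]] * C,
    G = p[["mu"]] - u * G,
    F = p[["omega"]] * Fa * (1 - Fa / p[["K"]]) - p[["theta"]] * N * Fa +
        p[["eta"]] * p[["sigma"]] * C * Fa,
    N = p[["s"]] * N * (1 - N / p[["M"]]) + p[["theta"]] * p[["nu"]] * N * Fa -
        p[["pi"]] * C * N)
}

#' Adjoint (costate) vector field
#'
#' The Pontryagin adjoint equations `u_i' = -dH/dx_i` for the Hamiltonian
#' of the CO2-minimisation problem with running cost
#' `A C + (B/2) u^2`:
#' \deqn{u_1' = -A + u_1(\eta F + p) - u_3 \eta\sigma F + u_4 \pi N}
#' \deqn{u_2' = u_1(u - \beta) + u_2 u}
#' \deqn{u_3' = u_1 \eta C - u_3[\omega(1 - 2F/K) - \theta N + \eta\sigma C]
#'   - u_4 \theta\nu N}
#' \deqn{u_4' = -u_1 \phi + u_3 \theta F -
#'   u_4[s(1 - 2N/M) + \theta\nu F - \pi C]}
#'
#' @param state state `(C, G, F, N)`.
#' @param adjoint numeric length-4 adjoint `(u1, u2, u3, u4)`.
#' @param u control value.
#' @param params a [carbo_params()] set.
#' @param A weight on the CO2 term of the running cost.
#' @return Numeric length-4 adjoint derivative.
#' @export
adjoint_rhs <- function(state, adjoint, u, params, A) {
  x <- as_state(state)
  if (any(!is.finite(adjoint))) stop("non-finite adjoint", call. = FALSE)
  p <- as_carbo_params(params)
  C <- x[[1]]; Fa <- x[[3]]; N <- x[[4]]
  l1 <- adjoint[1]; l3 <- adjoint[3]; l4 <- adjoint[4]
  c(-A + l1 * (p[["eta"]] * Fa + p[["p"]]) -
      l3 * p[["eta"]] * p[["sigma"]] * Fa + l4 * p[["pi"]] * N,
    l1 * (u - p[["beta"]]) + adjoint[2] * u,
    l1 * p[["eta"]] * C -
      l3 * (p[["omega"]] * (1 - 2 * Fa / p[["K"]]) - p[["theta"]] * N +
              p[["eta"]] * p[["sigma"]] * C) -
      l4 * p[["theta"]] * p[["nu"]] * N,
    -l1 * p[["phi"]] + l3 * p[["theta"]] * Fa -
      l4 * (p[["s"]] * (1 - 2 * N / p[["M"]]) +
              p[["theta"]] * p[["nu"]] * Fa - p[["pi"]] * C))
}

#' Hamiltonian of the control problem
#'
#' `H = A C + (B/2) u^2 + <adjoint, controlled_rhs>`. Exposed for
#' stationarity diagnostics and finite-difference checks.
#'
#' @inheritParams adjoint_rhs
#' @param B weight on the quadratic control cost.
#' @return Scalar Hamiltonian value.
#' @export
hamiltonian <- function(state, adjoint, u, params, A, B) {
  x <- as_state(state)
  A * x[["C"]] + B / 2 * u^2 +
    sum(adjoint * controlled_rhs(x, u, params))
}

#' Projected control update
#'
#' The Hamiltonian minimiser clipped to the admissible box:
#' `u* = max(0, min(u_max, (u1 + u2) G / B))`.
#'
#' @param u1,u2 CO2 and GDP adjoint values (vectors allowed).
#' @param G GDP value(s).
#' @param B quadratic cost weight, `> 0`.
#' @param u_max control upper bound.
#' @return Candidate control value(s) in `[0, u_max]`.
#' @export
control_update <- function(u1, u2, G, B, u_max) {
  if (B <= 0) stop("B must be positive", call. = FALSE)
  pmax(0, pmin(u_max, (u1 + u2) * G / B))
}

#' Objective functional
#'
#' Composite trapezoidal quadrature of `A C(t) + (B/2) u(t)^2` over the
#' trajectory grid.
#'
#' @param times time grid.
#' @param C CO2 path on the grid.
#' @param u control path on the same grid.
#' @param A,B objective weights.
#' @return Scalar objective value `J`.
#' @export
control_objective <- function(times, C, u, A, B) {
  if (length(times) != length(C) || length(times) != length(u)) {
    stop("times, C and u must share one grid", call. = FALSE)
  }
  integrand <- A * C + B / 2 * u^2
  sum(diff(times) * (integrand[-1] + integrand[-length(integrand)]) / 2)
}

# Fixed-step RK4 forward pass of the controlled system on a uniform grid.
# u is a vector on the grid (length n_steps + 1); midpoint control is the
# average of the two endpoint values.
rk4_forward <- function(params, init, u, dt) {
  p <- as_carbo_params(params)
  np1 <- length(u)
  X <- matrix(0, np1, 4)
  X[1, ] <- as_state(init)
  f <- function(x, uu) unname(controlled_rhs(x, uu, p))
  for (i in seq_len(np1 - 1)) {
    x <- X[i, ]
    um <- 0.5 * (u[i] + u[i + 1])
    k1 <- f(x, u[i])
    k2 <- f(x + 0.5 * dt * k1, um)
    k3 <- f(x + 0.5 * dt * k2, um)
    k4 <- f(x + dt * k3, u[i + 1])
    X[i + 1, ] <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  colnames(X) <- c("C", "G", "F", "N")
  X
}

# Backward RK4 adjoint pass with zero terminal conditions.
rk4_backward <- function(params, X, u, dt, A) {
  p <- as_carbo_params(params)
  np1 <- length(u)
  L <- matrix(0, np1, 4)
  g <- function(x, l, uu) adjoint_rhs(x, l, uu, p, A)
  for (i in seq(np1, 2)) {
    xi <- X[i, ]; xm <- 0.5 * (X[i - 1, ] + X[i, ]); xo <- X[i - 1, ]
    um <- 0.5 * (u[i - 1] + u[i])
    l <- L[i, ]
    k1 <- g(xi, l, u[i])
    k2 <- g(xm, l - 0.5 * dt * k1, um)
    k3 <- g(xm, l - 0.5 * dt * k2, um)
    k4 <- g(xo, l - dt * k3, u[i - 1])
    L[i - 1, ] <- l - dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  L
}

#' Solve the optimal-control problem by forward-backward sweep
#'
#' Iterates a fixed-grid fourth-order Runge-Kutta forward pass of the
#' controlled state system, a backward adjoint pass with zero terminal
#' conditions, and the relaxed projected control update
#' `u <- (1 - rho) u + rho * clip((u1 + u2) G / B)` until the joint
#' relative sup-norm change of control, states and adjoints falls below
#' `tol`.
#'
#' @param params a [carbo_params()] set.
#' @param init initial state `(C, G, F, N)`.
#' @param A,B objective weights (`B > 0`).
#' @param u_max control upper bound (`>= 0`).
#' @param t_f horizon (years, `> 0`).
#' @param n_steps number of uniform RK4 steps on `[0, t_f]`.
#' @param rho relaxation factor in `(0, 1]`.
#' @param tol convergence tolerance on the joint relative change.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with `converged = FALSE`.
#' @return A `carbo_control` list: `times`, `states` (matrix `C,G,F,N`),
#'   `adjoints`, `u`, `J`, `J_uncontrolled` (objective of the `u = 0`
#'   trajectory), `iterations`, `converged`, `trace` (per-iteration
#'   relative change).
#' @export
forward_backward_sweep <- function(params, init,
                                   A = 1e-4, B = 10, u_max = 0.008,
                                   t_f = 100, n_steps = 10000,
                                   rho = 0.5, tol = 1e-3, max_iter = 200) {
  stopifnot(B > 0, u_max >= 0, t_f > 0, n_steps >= 2, rho > 0, rho <= 1)
  p <- as_carbo_params(params)
  dt <- t_f / n_steps
  times <- seq(0, t_f, length.out = n_steps + 1)
  u <- rep(0, n_steps + 1)
  X <- rk4_forward(p, init, u, dt)
  L <- rk4_backward(p, X, u, dt, A)
  J0 <- control_objective(times, X[, "C"], rep(0, n_steps + 1), A, B)
  relchange <- function(new, old) {
    max(abs(new - old)) / (max(abs(new)) + 1e-12)
  }
  converged <- FALSE
  trace <- numeric(0)
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    u_cand <- control_update(L[, 1], L[, 2], X[, "G"], B, u_max)
    u_new <- (1 - rho) * u + rho * u_cand
    X_new <- rk4_forward(p, init, u_new, dt)
    L_new <- rk4_backward(p, X_new, u_new, dt, A)
    delta <- max(relchange(u_new, u), relchange(X_new, X),
                 relchange(L_new, L))
    trace <- c(trace, delta)
    u <- u_new; X <- X_new; L <- L_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("sweep did not converge in %d iterations (last change %.3g)",
                    max_iter, utils::tail(trace, 1)))
  }
  J <- control_objective(times, X[, "C"], u, A, B)
  structure(list(times = times, states = X, adjoints = L, u = u,
                 J = J, J_uncontrolled = J0,
                 iterations = it, converged = converged, trace = trace,
                 settings = list(A = A, B = B, u_max = u_max, t_f = t_f,
                                 n_steps = n_steps, rho = rho, tol = tol)),
            class = "carbo_control")
}

#' Integrate the controlled system under a fixed control path
#'
#' Forward RK4 pass only, for comparing policies (e.g. the uncontrolled
#' `u = 0` or the maximal constant effort) against the optimised control.
#'
#' @param params a [carbo_params()] set.
#' @param init initial state.
#' @param u control path: scalar (held constant) or vector on the grid.
#' @param t_f horizon (years).
#' @param n_steps number of uniform RK4 steps.
#' @return List with `times` and `states`.
#' @export
simulate_controlled <- function(params, init, u, t_f, n_steps = 10000) {
  dt <- t_f / n_steps
  if (length(u) == 1) u <- rep(u, n_steps + 1)
  stopifnot(length(u) == n_steps + 1)
  list(times = seq(0, t_f, length.out = n_steps + 1),
       states = rk4_forward(params, init, u, dt))
}

#' @export
print.carbo_control <- function(x, ...) {
  cat(sprintf("optimal control: J = %.6g (uncontrolled %.6g), %d iterations, converged = %s\n",
              x$J, x$J_uncontrolled, x$iterations, x$converged))
  invisible(x)
}
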