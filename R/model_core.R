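#' Model vector field
#'
#' Right-hand side of the four-compartment system
#' \deqn{dC/dt = \alpha + \phi N + (\beta - \varepsilon)G - \eta C F - p C}
#' \deqn{dG/dt = \mu - \varepsilon G}
#' \deqn{dF/dt = \omega F (1 - F/K) - \theta N F + \eta\sigma C F}
#' \deqn{dN/dt = s N (1 - N/M) + \theta\nu N F - \pi C N}
#' in units per year. The GDP equation is linear and decoupled: `dG/dt`
#' depends on `G` only.
#'
#' @param state numeric length-4 state `(C, G, F, N)`: CO2 (ppm), GDP
#'   (billion USD), forest area (million hectares), population (million).
#' @param params a [carbo_params()] set.
#' @return Named numeric derivative vector `(C, G, F, N)` per year.
#' @examples
#' model_rhs(c(0, 0, 0, 0), carbo_params())  # (alpha, mu, 0, 0)
#' @export
model_rhs <- function(state, params) {
  x <- as_state(state)
  p <- as_carbo_params(params)
  C <- x[[1]]; G <- x[[2]]; Fa <- x[[3]]; N <- x[[4]]
  c(C = p[["alpha"]] + p[["phi"]] * N + (p[["beta"]] - p[["epsilon"]]) * G -
        p[["eta"]] * C * Fa - p[["p"]] * C,
    G = p[["mu"]] - p[["epsilon"]] * G,
    F = p[["omega"]] * Fa * (1 - Fa / p[["K"]]) - p[["theta"]] * N * Fa +
        p[["eta"]] * p[["sigma"]] * C * Fa,
    N = p[["s"]] * N * (1 - N / p[["M"]]) + p[["theta"]] * p[["nu"]] * N * Fa -
        p[["pi"]] * C * N)
}

#' Model Jacobian matrix
#'
#' The 4x4 Jacobian of [model_rhs()] at a state, in 1/yr. The GDP row is
#' `(0, -epsilon, 0, 0)`, so `-epsilon` is an eigenvalue at every state.
#'
#' @inheritParams model_rhs
#' @return A 4x4 numeric matrix with rows/columns named `C, G, F, N`.
#' @export
model_jacobian <- function(state, params) {
  x <- as_state(state)
  p <- as_carbo_params(params)
  C <- x[[1]]; Fa <- x[[3]]; N <- x[[4]]
  J <- matrix(c(
    -p[["eta"]] * Fa - p[["p"]], p[["beta"]] - p[["epsilon"]],
      -p[["eta"]] * C, p[["phi"]],
    0, -p[["epsilon"]], 0, 0,
    p[["eta"]] * p[["sigma"]] * Fa, 0,
      p[["omega"]] - 2 * p[["omega"]] * Fa / p[["K"]] - p[["theta"]] * N +
        p[["eta"]] * p[["sigma"]] * C,
      -p[["theta"]] * Fa,
    -p[["pi"]] * N, 0, p[["nu"]] * p[["theta"]] * N,
      p[["s"]] - 2 * p[["s"]] * N / p[["M"]] +
        p[["nu"]] * p[["theta"]] * Fa - p[["pi"]] * C
  ), nrow = 4, byrow = TRUE)
  dimnames(J) <- list(c("C", "G", "F", "N"), c("C", "G", "F", "N"))
  J
}

#' Integrate a model trajectory
#'
#' Solves the system with an adaptive stiff-capable integrator
#' (`deSolve::ode`, lsoda) and reports the state at every requested time.
#' The vector field preserves non-negativity for admissible parameters, so
#' states are never clipped; if any component falls below `-1e-9` the
#' trajectory is flagged and a warning issued (this indicates solver
#' trouble, not model behaviour).
#'
#' @param params a [carbo_params()] set.
#' @param init non-negative initial state `(C, G, F, N)`.
#' @param times strictly increasing output time grid (years), length >= 2.
#' @param rtol,atol relative / absolute solver tolerances.
#' @param method integration method passed to [deSolve::ode()].
#' @return A `carbo_trajectory`: a data frame with columns `t, C, G, F, N`
#'   and attributes `meta` (solver settings) and `negativity` (logical flag).
#' @export
simulate_model <- function(params, init, times, rtol = 1e-8, atol = 1e-10,
                           method = "lsoda") {
  p <- as_carbo_params(params)
  y0 <- as_state(init)
  if (any(y0 < 0)) stop("initial state must be non-negative", call. = FALSE)
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing with at least 2 points",
         call. = FALSE)
  }
  deriv <- function(t, y, parms) list(model_rhs(y, parms))
  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = p,
                      method = method, rtol = rtol, atol = atol,
                      maxsteps = 100000)
  out <- as.data.frame(out)
  names(out) <- c("t", "C", "G", "F", "N")
  if (nrow(out) < length(times) || any(!is.finite(as.matrix(out)))) {
    last_good <- if (nrow(out) > 0) max(out$t[stats::complete.cases(out)]) else times[1]
    stop(sprintf("integration failed; last good time %.6g", last_good),
         call. = FALSE)
  }
  neg <- any(as.matrix(out[, c("C", "G", "F", "N")]) < -1e-9)
  if (neg) warning("trajectory component fell below -1e-9; solver trouble")
  structure(out,
            class = c("carbo_trajectory", "data.frame"),
            meta = list(rtol = rtol, atol = atol, method = method),
            negativity = neg)
}

#' Invariant bounding region
#'
#' Upper bounds of the box that attracts all solutions starting in the
#' positive orthant:
#' \deqn{G_{max} = \mu/\varepsilon,\quad
#'       C_{max} = (\alpha + \phi N_{max} + (\beta-\varepsilon)G_{max})/p,}
#' \deqn{F_{max} = K(\omega + \eta\sigma C_{max})/\omega,\quad
#'       N_{max} = M + (\theta\nu M/s) F_{max}.}
#' The three coupled bounds are circular in `C_max`; after substitution they
#' reduce to one linear equation in `C_max`, which is solved exactly.
#'
#' @param params a [carbo_params()] set.
#' @return A list with `C_max`, `G_max`, `F_max`, `N_max` and `feasible`
#'   (whether `alpha + phi*N_max + (beta - epsilon)*G_max > 0`).
#' @export
invariant_region <- function(params) {
  p <- as_carbo_params(params)
  G_max <- p[["mu"]] / p[["epsilon"]]
  # F_max = K + bF * C_max ; N_max = aN + bN * C_max
  bF <- p[["K"]] * p[["eta"]] * p[["sigma"]] / p[["omega"]]
  aN <- p[["M"]] + p[["theta"]] * p[["nu"]] * p[["M"]] / p[["s"]] * p[["K"]]
  bN <- p[["theta"]] * p[["nu"]] * p[["M"]] / p[["s"]] * bF
  denom <- p[["p"]] - p[["phi"]] * bN
  if (denom <= 0) {
    stop("infeasible bounding region: non-positive denominator in the ",
         "linear solve for C_max (degenerate parameters)", call. = FALSE)
  }
  C_max <- (p[["alpha"]] + p[["phi"]] * aN +
              (p[["beta"]] - p[["epsilon"]]) * G_max) / denom
  F_max <- p[["K"]] + bF * C_max
  N_max <- aN + bN * C_max
  feasible <- p[["alpha"]] + p[["phi"]] * N_max +
    (p[["beta"]] - p[["epsilon"]]) * G_max > 0
  list(C_max = C_max, G_max = G_max, F_max = F_max, N_max = N_max,
       feasible = feasible)
}

#' Write a trajectory to CSV
#'
#' Header `t,C,G,F,N` (plus `u` for controlled trajectories), one row per
#' grid point, full float precision.
#'
#' @param traj a `carbo_trajectory` or data frame with those columns.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
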