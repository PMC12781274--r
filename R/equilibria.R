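#' Boundary equilibria
#'
#' Closed-form computation of the three boundary fixed points. All share
#' the GDP component `G* = mu/epsilon`.
#' \itemize{
#'   \item `E1 = (C1, G*, 0, 0)` with
#'     `C1 = (alpha + (beta - epsilon) G*) / p` (direct substitution into
#'     the CO2 balance; a dimensionally inconsistent variant of this
#'     expression circulates and is recorded in the `notes` attribute).
#'   \item `E2 = (C2, G*, F2, 0)`: eliminating `F` via the forest nullcline
#'     `F = K(omega + eta sigma C)/omega` leaves the quadratic
#'     `(eta^2 sigma K / omega) C^2 + (p + eta K) C - (alpha + (beta -
#'     epsilon) G*) = 0`, which has a unique positive root by Descartes'
#'     rule whenever `alpha epsilon + mu (beta - epsilon) > 0`.
#'   \item `E3 = (C3, G*, 0, N3)` from the linear pair of CO2 and
#'     population nullclines on the forest-free face.
#' }
#' Existence flags come from computed positivity of the components and a
#' vector-field residual below `1e-8`, not from the printed inequality
#' forms (see [existence_report()] for those).
#'
#' @param params a [carbo_params()] set.
#' @return A named list of three `carbo_equilibrium` objects (`E1`, `E2`,
#'   `E3`), each with fields `label`, `point`, `exists`, `residual`.
#' @export
boundary_equilibria <- function(params) {
  p <- as_carbo_params(params)
  Gs <- p[["mu"]] / p[["epsilon"]]
  q <- p[["alpha"]] + (p[["beta"]] - p[["epsilon"]]) * Gs

  # E1: F = N = 0
  C1 <- q / p[["p"]]
  E1 <- make_equilibrium("E1", c(C = C1, G = Gs, F = 0, N = 0), p,
                         exists = C1 > 0)
  attr(E1, "notes") <- list(
    C1_printed_variant = (p[["alpha"]] +
      (p[["beta"]] / p[["epsilon"]] - p[["mu"]])) / p[["p"]])

  # E2: N = 0; quadratic in C after eliminating F
  a2 <- p[["eta"]]^2 * p[["sigma"]] * p[["K"]] / p[["omega"]]
  b2 <- p[["p"]] + p[["eta"]] * p[["K"]]
  disc <- b2^2 + 4 * a2 * q
  if (disc < 0) {
    E2 <- make_equilibrium("E2", c(C = NA_real_, G = Gs, F = NA_real_, N = 0),
                           p, exists = FALSE)
    attr(E2, "failed_condition") <- "negative discriminant of the C quadratic"
  } else {
    # numerically stable positive-root form: the leading coefficient is
    # O(eta^2) and the textbook (-b + sqrt)/2a form cancels catastrophically
    C2 <- 2 * q / (b2 + sqrt(disc))
    F2 <- p[["K"]] * (p[["omega"]] + p[["eta"]] * p[["sigma"]] * C2) /
      p[["omega"]]
    E2 <- make_equilibrium("E2", c(C = C2, G = Gs, F = F2, N = 0), p,
                           exists = C2 > 0 && F2 > 0)
  }

  # E3: F = 0; linear pair in (C, N)
  numC <- p[["s"]] * (p[["epsilon"]] * (p[["alpha"]] + p[["phi"]] * p[["M"]]) +
                        p[["mu"]] * (p[["beta"]] - p[["epsilon"]]))
  denC <- p[["epsilon"]] * (p[["s"]] * p[["p"]] +
                              p[["pi"]] * p[["phi"]] * p[["M"]])
  C3 <- numC / denC
  N3 <- p[["M"]] * (1 - p[["pi"]] * C3 / p[["s"]])
  E3 <- make_equilibrium("E3", c(C = C3, G = Gs, F = 0, N = N3), p,
                         exists = C3 > 0 && N3 > 0)
  list(E1 = E1, E2 = E2, E3 = E3)
}

make_equilibrium <- function(label, point, params, exists) {
  residual <- if (any(!is.finite(point))) Inf else
    max(abs(model_rhs(point, params)))
  exists <- isTRUE(exists) && residual < 1e-8
  structure(list(label = label, point = point, exists = exists,
                 residual = residual),
            class = "carbo_equilibrium")
}

#' @export
print.carbo_equilibrium <- function(x, ...) {
  cat(sprintf("%s: exists=%s residual=%.3g\n", x$label, x$exists, x$residual))
  print(x$point)
  invisible(x)
}

# Reduced 3-D nullcline system in (C, F, N) with G eliminated (G = mu/eps):
#   g1 = alpha + phi N + (beta - eps) mu/eps - eta C F - p C        (CO2)
#   g2 = omega - (omega/K) F - theta N + eta sigma C                (forest, per capita)
#   g3 = s - (s/M) N + theta nu F - pi C                            (population, per capita)
reduced_system <- function(x, p, q) {
  C <- x[1]; Fa <- x[2]; N <- x[3]
  c(q + p[["phi"]] * N - p[["eta"]] * C * Fa - p[["p"]] * C,
    p[["omega"]] - p[["omega"]] / p[["K"]] * Fa - p[["theta"]] * N +
      p[["eta"]] * p[["sigma"]] * C,
    p[["s"]] - p[["s"]] / p[["M"]] * N + p[["theta"]] * p[["nu"]] * Fa -
      p[["pi"]] * C)
}

reduced_jacobian <- function(x, p) {
  C <- x[1]; Fa <- x[2]
  matrix(c(-p[["eta"]] * Fa - p[["p"]], -p[["eta"]] * C, p[["phi"]],
           p[["eta"]] * p[["sigma"]], -p[["omega"]] / p[["K"]], -p[["theta"]],
           -p[["pi"]], p[["theta"]] * p[["nu"]], -p[["s"]] / p[["M"]]),
         nrow = 3, byrow = TRUE)
}

#' Interior equilibrium
#'
#' Solves the three nullclines in `(C, F, N)` with `G = mu/epsilon`
#' eliminated analytically, by damped Newton iteration with the analytic
#' 3x3 Jacobian. The default initial guess is the midpoint of the
#' invariant bounding region; a steady-state integration fallback
#' (`t = 1e5`) is used if Newton stalls, and the result is optionally
#' cross-validated against that long-time endpoint.
#'
#' @param params a [carbo_params()] set.
#' @param guess optional starting state `(C, G, F, N)` (G entry ignored).
#' @param cross_validate integrate to `t = 1e5` from the guess and record
#'   the distance between the endpoint and the root (informative only).
#' @return A `carbo_equilibrium` labelled `E4`. `exists` is `TRUE` only if
#'   all four components are strictly positive and the full vector-field
#'   residual is below `1e-8`. When cross-validated, attribute
#'   `integration_distance` holds the max-norm distance to the long-time
#'   integration endpoint.
#' @export
interior_equilibrium <- function(params, guess = NULL, cross_validate = TRUE) {
  p <- as_carbo_params(params)
  Gs <- p[["mu"]] / p[["epsilon"]]
  q <- p[["alpha"]] + (p[["beta"]] - p[["epsilon"]]) * Gs
  region <- invariant_region(p)
  if (is.null(guess)) {
    x0 <- c(region$C_max, region$F_max, region$N_max) / 2
    start_state <- c(C = x0[1], G = Gs, F = x0[2], N = x0[3])
  } else {
    start_state <- as_state(guess)
    x0 <- start_state[c("C", "F", "N")]
  }

  root <- newton_damped(function(x) reduced_system(x, p, q),
                        function(x) reduced_jacobian(x, p), x0)
  if (!root$converged) {
    # fall back to steady-state integration, then polish
    traj <- try(simulate_model(p, pmax(start_state, 1e-6),
                               c(0, 1e5), rtol = 1e-10, atol = 1e-12),
                silent = TRUE)
    if (!inherits(traj, "try-error")) {
      xi <- unlist(traj[nrow(traj), c("C", "F", "N")])
      root <- newton_damped(function(x) reduced_system(x, p, q),
                            function(x) reduced_jacobian(x, p), xi)
    }
    if (!root$converged) {
      stop(sprintf(paste0("interior equilibrium root finding failed to ",
                          "converge; final residual %.3g"), root$fnorm),
           call. = FALSE)
    }
  }
  point <- c(C = root$x[1], G = Gs, F = root$x[2], N = root$x[3])
  eq <- make_equilibrium("E4", point, p,
                         exists = all(point > 0))
  if (cross_validate) {
    traj <- try(simulate_model(p, pmax(start_state, 1e-6), c(0, 1e5)),
                silent = TRUE)
    if (!inherits(traj, "try-error")) {
      endpoint <- unlist(traj[nrow(traj), c("C", "G", "F", "N")])
      attr(eq, "integration_distance") <- max(abs(endpoint - point))
    }
  }
  eq
}

# Damped Newton for small dense systems: full step, halved while the
# residual norm does not decrease.
newton_damped <- function(f, jac, x0, tol = 1e-12, max_iter = 100) {
  x <- as.numeric(x0)
  fx <- f(x)
  for (it in seq_len(max_iter)) {
    fn <- max(abs(fx))
    if (fn < tol) return(list(x = x, converged = TRUE, fnorm = fn, iter = it))
    step <- tryCatch(solve(jac(x), fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(x = x, converged = FALSE, fnorm = fn, iter = it))
    }
    lambda <- 1
    repeat {
      x_new <- x - lambda * step
      f_new <- f(x_new)
      if (all(is.finite(f_new)) && max(abs(f_new)) < fn) break
      lambda <- lambda / 2
      if (lambda < 1e-12) break
    }
    x <- x - lambda * step
    fx <- f(x)
  }
  list(x = x, converged = max(abs(fx)) < tol, fnorm = max(abs(fx)),
       iter = max_iter)
}

#' Conditional CO2/population steady state at fixed forest area
#'
#' With GDP at its steady state `mu/epsilon` and the forest area held
#' fixed, the CO2 and (per-capita) population nullclines are linear in
#' `(C, N)`; this solves that 2x2 system exactly. Used to check reported
#' interior-equilibrium components whose forest value is only available
#' rounded.
#'
#' @param params a [carbo_params()] set.
#' @param forest fixed forest area (million hectares).
#' @return Named numeric `c(C, N)`.
#' @export
solve_cn_at_forest <- function(params, forest) {
  p <- as_carbo_params(params)
  Gs <- p[["mu"]] / p[["epsilon"]]
  q <- p[["alpha"]] + (p[["beta"]] - p[["epsilon"]]) * Gs
  A <- matrix(c(p[["eta"]] * forest + p[["p"]], -p[["phi"]],
                p[["pi"]], p[["s"]] / p[["M"]]), 2, 2, byrow = TRUE)
  b <- c(q, p[["s"]] + p[["theta"]] * p[["nu"]] * forest)
  sol <- solve(A, b)
  c(C = sol[1], N = sol[2])
}

#' Existence-condition report
#'
#' Evaluates, numerically and verbatim, the printed existence inequalities
#' for the four equilibria, together with the intermediate nullcline
#' quantities `N_a`, `N_b` and `F_b` used in the interior-equilibrium
#' intersection argument. Several of the printed forms contain
#' typographical defects (they disagree with direct substitution); they
#' are reported exactly as printed, with both sides, and equilibrium
#' existence flags elsewhere rely on computed positivity instead.
#'
#' @param params a [carbo_params()] set.
#' @return A data frame with columns `id`, `lhs`, `op`, `rhs`, `satisfied`,
#'   and attribute `intermediates` (list with `N_a`, `N_b`, `F_b`).
#' @export
existence_report <- function(params) {
  p <- as_carbo_params(params)
  al <- p[["alpha"]]; ph <- p[["phi"]]; be <- p[["beta"]]; ep <- p[["epsilon"]]
  et <- p[["eta"]]; pp <- p[["p"]]; mu <- p[["mu"]]; om <- p[["omega"]]
  K <- p[["K"]]; th <- p[["theta"]]; sg <- p[["sigma"]]; s <- p[["s"]]
  M <- p[["M"]]; nu <- p[["nu"]]; pi_ <- p[["pi"]]

  rows <- list(
    list(id = "6",  lhs = al + (1 - be / ep), op = ">", rhs = 0),
    list(id = "10", lhs = al * ep + mu * (be - ep), op = ">", rhs = 0),
    list(id = "15", lhs = ep * (al + ph * M) + mu * (be - ep), op = ">",
         rhs = 0),
    list(id = "16", lhs = ep * (s * pp + pi_ * ph * M), op = ">",
         rhs = ep * (al + ph * M) + mu * (be - ep)),
    list(id = "21",
         lhs = (ep * pp * (s * pp + pi_ * ph * M)) *
           (ep * om * pp + et * sg * (ep * al + mu * (be - ep))),
         op = ">",
         rhs = ep * M * (pp * th - et * sg * ph) *
           (ep * (al + s * pi_ * pp) + mu * (be - ep))),
    list(id = "28", lhs = pp * th - et * sg * ph, op = ">", rhs = 0),
    list(id = "30", lhs = ep * (al + s * pi_ * pp) + mu * (be - ep),
         op = ">", rhs = 0),
    list(id = "32", lhs = ep * (s * pp - al) - (be - ep), op = "<", rhs = 0)
  )
  df <- do.call(rbind, lapply(rows, function(r) {
    sat <- if (!is.finite(r$lhs) || !is.finite(r$rhs)) NA
           else if (r$op == ">") r$lhs > r$rhs else r$lhs < r$rhs
    data.frame(id = r$id, lhs = r$lhs, op = r$op, rhs = r$rhs,
               satisfied = sat, stringsAsFactors = FALSE)
  }))

  N_a_den <- ep * (pp * th - et * sg * ph)
  N_a <- if (N_a_den == 0) NA_real_ else
    (ep * om * pp + et * sg * (ep * al + mu * (be - ep))) / N_a_den
  N_b_den <- ep * pp * (s * pp + pi_ * ph * M)
  N_b <- if (N_b_den == 0) NA_real_ else
    M * (ep * (al + s * pi_ * pp) + mu * (be - ep)) / N_b_den
  # F_b: root of nu*eps*eta*theta F^2 + s*eps*(eta + nu p) F
  #        + [eps(sp - alpha) - (beta - eps)] = 0 (the negative root when
  # condition (32) holds)
  aF <- nu * ep * et * th; bF <- s * ep * (et + nu * pp)
  cF <- ep * (s * pp - al) - (be - ep)
  discF <- bF^2 - 4 * aF * cF
  F_b <- if (aF == 0 || discF < 0) NA_real_ else (-bF - sqrt(discF)) / (2 * aF)
  attr(df, "intermediates") <- list(N_a = N_a, N_b = N_b, F_b = F_b)
  df
}
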