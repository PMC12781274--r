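#' Local stability report at an equilibrium
#'
#' Eigenvalues of the full 4x4 Jacobian at an equilibrium point, a
#' stability classification, and the directional condition checks relevant
#' to that equilibrium's face. Because the GDP row of the Jacobian is
#' `(0, -epsilon, 0, 0)`, `-epsilon` is always among the eigenvalues.
#'
#' Directional closed forms (from the block structure of the Jacobian):
#' the carbon-free-forest/population point `E1` has eigenvalues
#' `{-p, -epsilon, omega + eta sigma C1, s - pi C1}` and is unstable
#' whenever it exists since `omega + eta sigma C1 > 0`; `E2`'s
#' population-direction eigenvalue is `s + nu theta F2 - pi C2`; `E3`'s
#' forest-direction eigenvalue is `omega - theta N3 + eta sigma C3`.
#'
#' @param eq a `carbo_equilibrium` (from [boundary_equilibria()] or
#'   [interior_equilibrium()]).
#' @param params a [carbo_params()] set.
#' @return A list of class `carbo_stability` with `eigenvalues` (complex,
#'   sorted by real part), `classification` (`"stable"`, `"unstable"` or
#'   `"marginal"`), and `condition_checks` (data frame `id, lhs, op, rhs,
#'   satisfied`). Real parts within `1e-12` of zero are classified
#'   marginal, not stable.
#' @export
stability_report <- function(eq, params) {
  stopifnot(inherits(eq, "carbo_equilibrium"))
  if (!isTRUE(eq$exists)) stop("equilibrium does not exist; no stability report",
                               call. = FALSE)
  p <- as_carbo_params(params)
  J <- model_jacobian(eq$point, p)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(Re(ev))]
  re <- Re(ev)
  classification <- if (any(abs(re) < 1e-12)) "marginal"
    else if (all(re < 0)) "stable" else "unstable"

  checks <- directional_checks(eq, p)
  structure(list(label = eq$label, eigenvalues = ev,
                 classification = classification,
                 condition_checks = checks),
            class = "carbo_stability")
}

directional_checks <- function(eq, p) {
  pt <- eq$point
  C <- pt[["C"]]; Fa <- pt[["F"]]; N <- pt[["N"]]
  om <- p[["omega"]]; K <- p[["K"]]; et <- p[["eta"]]; sg <- p[["sigma"]]
  s <- p[["s"]]; M <- p[["M"]]; pi_ <- p[["pi"]]; pp <- p[["p"]]
  th <- p[["theta"]]; nu <- p[["nu"]]; ph <- p[["phi"]]
  if (eq$label == "E1") {
    data.frame(id = "E1_forest_growth", lhs = om + et * sg * C, op = ">",
               rhs = 0, satisfied = om + et * sg * C > 0)
  } else if (eq$label == "E2") {
    lhs35 <- om - 2 * om * Fa / K + et * sg * C
    rhs35 <- min(et * Fa + pp, sg * et^2 * Fa * C / (et * Fa + pp))
    rbind(
      data.frame(id = "E2_population_direction", lhs = s + nu * th * Fa -
                   pi_ * C, op = "<", rhs = 0,
                 satisfied = s + nu * th * Fa - pi_ * C < 0),
      data.frame(id = "35", lhs = lhs35, op = "<", rhs = rhs35,
                 satisfied = lhs35 < rhs35))
  } else if (eq$label == "E3") {
    lhs36 <- s - 2 * s * N / M - pi_ * C
    rhs36 <- min(pp, pi_ * ph * N / pp)
    rbind(
      data.frame(id = "E3_forest_direction", lhs = om - th * N + et * sg * C,
                 op = "<", rhs = 0,
                 satisfied = om - th * N + et * sg * C < 0),
      data.frame(id = "36", lhs = lhs36, op = "<", rhs = rhs36,
                 satisfied = lhs36 < rhs36))
  } else {
    cc <- cubic_coefficients(eq, p)
    data.frame(id = "37", lhs = cc$charpoly[["A1"]] * cc$charpoly[["A2"]] -
                 cc$charpoly[["A3"]], op = ">", rhs = 0,
               satisfied = cc$hurwitz_ok)
  }
}

#' @export
print.carbo_stability <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$label, x$classification))
  print(x$eigenvalues)
  invisible(x)
}

# Characteristic cubic coefficients of a 3x3 matrix:
# psi^3 + A1 psi^2 + A2 psi + A3 with A1 = -tr, A2 = sum of principal
# 2x2 minors, A3 = -det.
cubic_from_matrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)))
  A1 <- -sum(diag(m))
  A2 <- (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) +
        (m[1, 1] * m[3, 3] - m[1, 3] * m[3, 1]) +
        (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2])
  A3 <- -det(m)
  c(A1 = A1, A2 = A2, A3 = A3)
}

#' Routh-Hurwitz cubic coefficients at the interior equilibrium
#'
#' After factoring out the decoupled GDP eigenvalue `-epsilon`, the
#' characteristic polynomial of the Jacobian at the interior equilibrium
#' is the cubic `psi^3 + A1 psi^2 + A2 psi + A3`. Two variants are
#' computed:
#' \itemize{
#'   \item `charpoly` (authoritative): coefficients of the reduced 3x3
#'     Jacobian in the `(C, F, N)` directions after applying the
#'     equilibrium nullcline identities (the forest and population
#'     diagonal entries collapse to `-omega F/K` and `-s N/M`).
#'   \item `paper`: a previously published closed-form expression set,
#'     retained verbatim for comparison; it disagrees with the
#'     characteristic polynomial (extra `2 omega F/K` and `2 nu theta F`
#'     terms) and is never used for the stability verdict.
#' }
#' The Hurwitz verdict for the cubic is `A1, A2, A3 > 0` and
#' `A1 A2 - A3 > 0`, evaluated on the `charpoly` values.
#'
#' @param eq the interior `carbo_equilibrium` (label `E4`).
#' @param params a [carbo_params()] set.
#' @return List with `charpoly`, `paper` (each `c(A1, A2, A3)`) and
#'   `hurwitz_ok`.
#' @export
cubic_coefficients <- function(eq, params) {
  stopifnot(inherits(eq, "carbo_equilibrium"))
  if (eq$label != "E4" || any(eq$point <= 0)) {
    stop("cubic coefficients are defined for the interior equilibrium only",
         call. = FALSE)
  }
  p <- as_carbo_params(params)
  C <- eq$point[["C"]]; Fa <- eq$point[["F"]]; N <- eq$point[["N"]]
  et <- p[["eta"]]; pp <- p[["p"]]; om <- p[["omega"]]; K <- p[["K"]]
  th <- p[["theta"]]; sg <- p[["sigma"]]; s <- p[["s"]]; M <- p[["M"]]
  nu <- p[["nu"]]; ph <- p[["phi"]]; pi_ <- p[["pi"]]

  # reduced Jacobian with nullcline identities applied on the diagonal
  m <- matrix(c(-et * Fa - pp, -et * C, ph,
                et * sg * Fa, -om * Fa / K, -th * Fa,
                -pi_ * N, nu * th * N, -s * N / M),
              3, 3, byrow = TRUE)
  cp <- cubic_from_matrix(m)

  A1p <- et * Fa + pp + 2 * om / K * Fa + 2 * nu * th * Fa + s / M * N
  A2p <- (om / K * Fa) * (s / M * N) +
    (pp + et * Fa) * (om / K * Fa + s / M * N)
  A3p <- s / M * et * th * (pi_ * C + nu * sg * ph) * N^2 * Fa +
    (om / K * pi_ * ph + nu * th^2 * (et * Fa + pp)) * N * Fa +
    om / K * s / M * et^2 * sg * N * Fa^2
  hurwitz_ok <- all(cp > 0) && (cp[["A1"]] * cp[["A2"]] - cp[["A3"]] > 0)
  list(charpoly = cp, paper = c(A1 = A1p, A2 = A2p, A3 = A3p),
       hurwitz_ok = hurwitz_ok)
}

#' Lyapunov global-stability check
#'
#' The candidate Lyapunov function anchored at the interior equilibrium is
#' \deqn{V = \tfrac12 (C - C_4)^2 + \tfrac12 (G - G_4)^2
#'   + m_1 (F - F_4 - F_4 \log(F/F_4)) + m_2 (N - N_4 - N_4 \log(N/N_4))}
#' with weights `m2 = phi/pi` and `m1 = nu m2` chosen to cancel the
#' population--CO2 and forest--population cross terms. Negative
#' definiteness of `dV/dt` inside the bounding region requires
#' \deqn{\max\{\eta^2 K/(m_1\omega)\,(m_1\sigma - C_{max})^2,\;
#'   (\beta-\varepsilon)^2/\varepsilon\} < 2(p + \eta F_4).}
#' The statement of this condition also circulates with `eta` to the first
#' power in the first brace term; both are evaluated and reported, but the
#' squared (proof-consistent) form drives the `satisfied` flag.
#'
#' @param params a [carbo_params()] set.
#' @param eq4 the interior `carbo_equilibrium`.
#' @param region the [invariant_region()] of `params` (computed if `NULL`).
#' @return List with `m1`, `m2`, `lhs_printed`, `lhs_proof`, `rhs`,
#'   `satisfied_printed`, `satisfied_proof` and the individual brace terms.
#' @export
global_stability_check <- function(params, eq4, region = NULL) {
  p <- as_carbo_params(params)
  stopifnot(inherits(eq4, "carbo_equilibrium"), eq4$label == "E4")
  if (p[["pi"]] == 0) stop("pi = 0: Lyapunov weights m1, m2 undefined",
                           call. = FALSE)
  if (is.null(region)) region <- invariant_region(p)
  if (!isTRUE(region$feasible)) stop("bounding region not feasible",
                                     call. = FALSE)
  m2 <- p[["phi"]] / p[["pi"]]
  m1 <- p[["nu"]] * m2
  F4 <- eq4$point[["F"]]
  cross <- (m1 * p[["sigma"]] - region$C_max)^2 * p[["K"]] /
    (m1 * p[["omega"]])
  term_printed <- p[["eta"]] * cross
  term_proof <- p[["eta"]]^2 * cross
  term_gdp <- (p[["beta"]] - p[["epsilon"]])^2 / p[["epsilon"]]
  rhs <- 2 * (p[["p"]] + p[["eta"]] * F4)
  list(m1 = m1, m2 = m2,
       term_forest_printed = term_printed,
       term_forest_proof = term_proof,
       term_gdp = term_gdp,
       lhs_printed = max(term_printed, term_gdp),
       lhs_proof = max(term_proof, term_gdp),
       rhs = rhs,
       satisfied_printed = max(term_printed, term_gdp) < rhs,
       satisfied_proof = max(term_proof, term_gdp) < rhs)
}

#' Evaluate the Lyapunov function at a state
#'
#' @param state state `(C, G, F, N)` with `F, N > 0`.
#' @param eq4 the interior `carbo_equilibrium` anchoring `V`.
#' @param m1,m2 positive weights (see [global_stability_check()]).
#' @return The scalar value of `V` (zero exactly at the equilibrium).
#' @export
lyapunov_value <- function(state, eq4, m1, m2) {
  x <- as_state(state)
  if (x[["F"]] <= 0 || x[["N"]] <= 0) {
    stop("Lyapunov function undefined: F and N must be positive",
         call. = FALSE)
  }
  e <- eq4$point
  0.5 * (x[["C"]] - e[["C"]])^2 + 0.5 * (x[["G"]] - e[["G"]])^2 +
    m1 * (x[["F"]] - e[["F"]] - e[["F"]] * log(x[["F"]] / e[["F"]])) +
    m2 * (x[["N"]] - e[["N"]] - e[["N"]] * log(x[["N"]] / e[["N"]]))
}

#' Monotonicity of the Lyapunov function along a trajectory
#'
#' Evaluates `V` at every grid point of a trajectory and reports the
#' maximum increase between consecutive points (non-positive up to solver
#' noise when the global-stability condition holds).
#'
#' @param traj a `carbo_trajectory` strictly inside the positive orthant.
#' @param eq4 the interior `carbo_equilibrium`.
#' @param m1,m2 Lyapunov weights.
#' @return List with `V` (vector along the grid) and `max_increase`.
#' @export
lyapunov_check <- function(traj, eq4, m1, m2) {
  tr <- as.data.frame(traj)
  if (any(tr$F <= 0) || any(tr$N <= 0)) {
    stop("Lyapunov function undefined along trajectory: non-positive F or N",
         call. = FALSE)
  }
  V <- vapply(seq_len(nrow(tr)), function(i) {
    lyapunov_value(c(C = tr$C[i], G = tr$G[i], F = tr$F[i], N = tr$N[i]),
                   eq4, m1, m2)
  }, numeric(1))
  list(V = V, max_increase = max(diff(V)))
}
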