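# Shared fixtures and independent oracles used across the suite.

PARS <- carbo_params()           # baseline constants, eta = 1e-7
INIT <- c(C = 130, G = 0.121, F = 1003, N = 80)

# Independent route to the interior equilibrium: reduce to one equation in
# the forest area. Given F, the CO2 and forest nullclines are linear in
# (C, N); the population nullcline residual is then a scalar function of F
# bracketed and solved by uniroot. Entirely separate from the package's
# damped-Newton path.
interior_oracle <- function(pars) {
  Gs <- pars[["mu"]] / pars[["epsilon"]]
  q <- pars[["alpha"]] + (pars[["beta"]] - pars[["epsilon"]]) * Gs
  cn_given_F <- function(Fv) {
    C <- (q + pars[["phi"]] * pars[["omega"]] * (1 - Fv / pars[["K"]]) /
            pars[["theta"]]) /
      ((pars[["p"]] + pars[["eta"]] * Fv) -
         pars[["phi"]] * pars[["eta"]] * pars[["sigma"]] / pars[["theta"]])
    N <- (pars[["omega"]] * (1 - Fv / pars[["K"]]) +
            pars[["eta"]] * pars[["sigma"]] * C) / pars[["theta"]]
    c(C, N)
  }
  res <- function(Fv) {
    z <- cn_given_F(Fv)
    pars[["s"]] * (1 - z[2] / pars[["M"]]) +
      pars[["theta"]] * pars[["nu"]] * Fv - pars[["pi"]] * z[1]
  }
  Fr <- stats::uniroot(res, c(1, pars[["K"]] * 0.9999), tol = 1e-13)$root
  z <- cn_given_F(Fr)
  c(C = z[1], G = Gs, F = Fr, N = z[2])
}

# Central finite-difference Jacobian of a vector field.
fd_jacobian <- function(f, x, h_scale = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- h_scale * (1 + abs(x[j]))
    up <- x; up[j] <- up[j] + h
    dn <- x; dn[j] <- dn[j] - h
    J[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  J
}

# Partial correlation of columns i and j of a data matrix, controlling for
# every other column, via precision-matrix inversion.
partial_cor_oracle <- function(mat, i, j) {
  P <- solve(stats::cor(mat))
  -P[i, j] / sqrt(P[i, i] * P[j, j])
}

# Random admissible state inside a loose physical box.
rand_state <- function() {
  c(C = stats::runif(1, 1, 2000), G = stats::runif(1, 0.01, 30),
    F = stats::runif(1, 1, 11000), N = stats::runif(1, 0.1, 1700))
}

# Baseline parameters jittered uniformly within +/- `frac` of each value.
jitter_params <- function(frac = 0.1) {
  x <- as.numeric(PARS) * stats::runif(15, 1 - frac, 1 + frac)
  names(x) <- names(PARS)
  as_carbo_params(x)
}
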