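test_that("vector field matches hand-evaluated values at reference states", {
  # origin: forest and population axes are absorbing, constants remain
  expect_equal(unname(model_rhs(c(0, 0, 0, 0), PARS)),
               c(1.68, 0.02145, 0, 0))
  # hand evaluation of each term at (100, 10, 1000, 50)
  d <- model_rhs(c(100, 10, 1000, 50), PARS)
  expect_equal(unname(d), c(0.465, 0.01345, 35.75465, 0.026811),
               tolerance = 1e-6)
  # GDP equation depends on G only
  d2 <- model_rhs(c(500, 10, 5, 1000), PARS)
  expect_identical(d[["G"]], d2[["G"]])
})

test_that("non-finite states are rejected naming the offending component", {
  expect_error(model_rhs(c(NA, 1, 1, 1), PARS), "C")
  expect_error(model_rhs(c(1, 1, Inf, 1), PARS), "F")
  expect_error(model_jacobian(c(1, NaN, 1, 1), PARS), "G")
})

test_that("Jacobian has the decoupled GDP row and matches finite differences", {
  J0 <- model_jacobian(c(0, 0, 0, 0), PARS)
  expect_equal(unname(J0),
               matrix(c(-0.016, 0.0003 - 0.0008, 0, 0.008,
                        0, -0.0008, 0, 0,
                        0, 0, 0.06133, 0,
                        0, 0, 0, 0.00529), 4, 4, byrow = TRUE))
  set.seed(42)
  for (i in 1:100) {
    pars <- jitter_params()
    x <- rand_state()
    J <- model_jacobian(x, pars)
    expect_equal(J[2, ], c(C = 0, G = -pars[["epsilon"]], F = 0, N = 0))
    Jfd <- fd_jacobian(function(y) model_rhs(y, pars), x)
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
})

test_that("GDP subsystem matches its closed-form solution", {
  tr <- simulate_model(PARS, INIT, seq(0, 500, by = 5))
  Gs <- PARS[["mu"]] / PARS[["epsilon"]]
  closed <- Gs + (INIT[["G"]] - Gs) * exp(-PARS[["epsilon"]] * tr$t)
  expect_lt(max(abs(tr$G - closed)), 1e-8)
})

test_that("the computed interior equilibrium is a fixed point of the flow", {
  e4 <- interior_equilibrium(PARS, cross_validate = FALSE)
  expect_lt(max(abs(model_rhs(e4$point, PARS))), 1e-8)
  tr <- simulate_model(PARS, e4$point, seq(0, 100, by = 1))
  drift <- vapply(c("C", "G", "F", "N"),
                  function(v) max(abs(tr[[v]] - e4$point[[v]])), numeric(1))
  expect_lt(max(drift), 1e-6)
})

test_that("trajectories stay inside the invariant region and non-negative", {
  reg <- invariant_region(PARS)
  expect_true(reg$feasible)
  set.seed(7)
  for (i in 1:5) {
    init <- c(C = runif(1, 0, reg$C_max), G = runif(1, 0, reg$G_max),
              F = runif(1, 0, reg$F_max), N = runif(1, 0, reg$N_max))
    tr <- simulate_model(PARS, init, seq(0, 4000, length.out = 200))
    expect_gte(min(as.matrix(tr[, c("C", "G", "F", "N")])), -1e-9)
    expect_lte(max(tr$C), reg$C_max + 1e-6)
    expect_lte(max(tr$G), reg$G_max + 1e-6)
    expect_lte(max(tr$F), reg$F_max + 1e-6)
    expect_lte(max(tr$N), reg$N_max + 1e-6)
  }
})

test_that("invariant region solves the circular bound definitions exactly", {
  reg <- invariant_region(PARS)
  p <- PARS
  expect_identical(reg$G_max, p[["mu"]] / p[["epsilon"]])
  expect_equal(reg$G_max, 26.8125)
  # self-consistency of the three coupled bounds
  expect_equal(reg$C_max,
               (p[["alpha"]] + p[["phi"]] * reg$N_max +
                  (p[["beta"]] - p[["epsilon"]]) * reg$G_max) / p[["p"]])
  expect_equal(reg$F_max,
               p[["K"]] * (p[["omega"]] + p[["eta"]] * p[["sigma"]] *
                             reg$C_max) / p[["omega"]])
  expect_equal(reg$N_max,
               p[["M"]] + p[["theta"]] * p[["nu"]] * p[["M"]] / p[["s"]] *
                 reg$F_max)
  # fixed-point iteration of the bound maps from (0, 0, 0) reaches the
  # same point (independent route to the linear solve)
  Cm <- 0; Fm <- 0; Nm <- 0
  for (i in 1:50) {
    Cm <- (p[["alpha"]] + p[["phi"]] * Nm +
             (p[["beta"]] - p[["epsilon"]]) * reg$G_max) / p[["p"]]
    Fm <- p[["K"]] * (p[["omega"]] + p[["eta"]] * p[["sigma"]] * Cm) /
      p[["omega"]]
    Nm <- p[["M"]] + p[["theta"]] * p[["nu"]] * p[["M"]] / p[["s"]] * Fm
  }
  expect_equal(Cm, reg$C_max, tolerance = 1e-6)
  expect_equal(Fm, reg$F_max, tolerance = 1e-6)
  expect_equal(Nm, reg$N_max, tolerance = 1e-6)
})

test_that("decoupled bounds collapse to the closed chain when phi = sigma = 0", {
  p0 <- PARS
  p0[c("phi", "sigma")] <- 0
  p0 <- as_carbo_params(unclass(p0))
  reg <- invariant_region(p0)
  Gm <- p0[["mu"]] / p0[["epsilon"]]
  Cm <- (p0[["alpha"]] + (p0[["beta"]] - p0[["epsilon"]]) * Gm) / p0[["p"]]
  expect_equal(reg$C_max, Cm)
  expect_equal(reg$F_max, p0[["K"]])
  expect_equal(reg$N_max,
               p0[["M"]] + p0[["theta"]] * p0[["nu"]] * p0[["M"]] *
                 p0[["K"]] / p0[["s"]])
})

test_that("trajectory CSV round-trips with the documented header", {
  tr <- simulate_model(PARS, INIT, 0:10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  expect_identical(readLines(f, n = 1), "t,C,G,F,N")
  back <- utils::read.csv(f)
  expect_equal(back$C, tr$C)
})
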