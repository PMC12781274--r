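#' @keywords internal
"_PACKAGE"

# Canonical parameter order used throughout the package.
PARAM_NAMES <- c("alpha", "phi", "beta", "epsilon", "eta", "p", "mu",
                 "omega", "K", "theta", "sigma", "s", "M", "nu", "pi")

#' Model parameter set
#'
#' Construct the 15-constant parameter set of the coupled
#' CO2--GDP--forest--population model. Defaults are the calibrated
#' China-2000--2022 baseline values. The forest absorption coefficient
#' `eta` is reported in the source material with two values that differ by
#' a factor of ten; `eta_variant` selects between them (`"text"`, the
#' default, gives `1e-7`; `"table1"` gives `1e-6`). An explicit `eta`
#' argument overrides either variant.
#'
#' @param alpha natural CO2 emission rate (ppm / yr).
#' @param phi anthropogenic CO2 emission rate per population
#'   (ppm / yr per million persons).
#' @param beta GDP-driven CO2 emission coefficient (ppm / yr per billion USD).
#' @param epsilon GDP decay rate, also the GDP-driven CO2 abatement rate
#'   (1 / yr). Must be positive: the GDP bound is `mu / epsilon`.
#' @param eta forest CO2 depletion coefficient (per million hectares / yr).
#' @param p natural CO2 decay rate (1 / yr).
#' @param mu GDP inflow rate (billion USD / yr).
#' @param omega forest intrinsic growth rate (1 / yr).
#' @param K forest carrying capacity (million hectares).
#' @param theta deforestation rate per population (1 / yr per million persons).
#' @param sigma forest growth gain from CO2 absorption (dimensionless
#'   multiplier on `eta`).
#' @param s population intrinsic growth rate (1 / yr).
#' @param M population carrying capacity (million persons).
#' @param nu population gain from forest (dimensionless multiplier on `theta`).
#' @param pi_ CO2-induced mortality coefficient (1 / yr / ppm). Named with a
#'   trailing underscore to avoid masking [base::pi]; the stored field is
#'   `pi`.
#' @param eta_variant which reported value of `eta` to use when `eta` is not
#'   given explicitly: `"text"` (1e-7) or `"table1"` (1e-6).
#'
#' @return An object of class `carbo_params`: a named numeric vector of the
#'   15 constants in canonical order.
#' @examples
#' pars <- carbo_params()
#' pars[["mu"]] / pars[["epsilon"]]  # steady-state GDP, 26.8125
#' @export
carbo_params <- function(alpha = 1.68, phi = 0.008, beta = 0.0003,
                         epsilon = 0.0008, eta = NULL, p = 0.016,
                         mu = 0.02145, omega = 0.06133, K = 11000,
                         theta = 0.0004, sigma = 0.01, s = 0.00529,
                         M = 1720, nu = 0.001, pi_ = 0.00005,
                         eta_variant = c("text", "table1")) {
  eta_variant <- match.arg(eta_variant)
  if (is.null(eta)) {
    eta <- if (eta_variant == "text") 1e-7 else 1e-6
  }
  x <- c(alpha = alpha, phi = phi, beta = beta, epsilon = epsilon, eta = eta,
         p = p, mu = mu, omega = omega, K = K, theta = theta, sigma = sigma,
         s = s, M = M, nu = nu, pi = pi_)
  x <- x[PARAM_NAMES]
  validate_params(x)
  structure(x, class = "carbo_params")
}

validate_params <- function(x) {
  if (!is.numeric(x) || length(x) != 15L || !all(PARAM_NAMES %in% names(x))) {
    stop("parameter set must contain the 15 named model constants: ",
         paste(PARAM_NAMES, collapse = ", "), call. = FALSE)
  }
  bad <- names(x)[!is.finite(x) | x < 0]
  if (length(bad) > 0) {
    stop("parameters must be finite and non-negative; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # rates and capacities that appear in denominators must be positive
  strict <- c("epsilon", "p", "omega", "K", "s", "M")
  bad <- strict[x[strict] <= 0]
  if (length(bad) > 0) {
    stop("parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Coerce a named vector or list to a parameter set
#'
#' @param x a `carbo_params`, named numeric vector, or named list holding the
#'   15 model constants.
#' @return A validated `carbo_params` object.
#' @export
as_carbo_params <- function(x) {
  if (inherits(x, "carbo_params")) return(x)
  x <- unlist(x)
  validate_params(x)
  structure(x[PARAM_NAMES], class = "carbo_params")
}

#' @export
print.carbo_params <- function(x, ...) {
  cat("Model parameter set (15 constants):\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Baseline sampling intervals for sensitivity analysis
#'
#' Per-parameter `[lo, hi]` ranges used for the Latin hypercube design,
#' roughly +/- 10 percent around the baselines (the forest absorption
#' coefficient interval brackets its larger, 1e-6 reported value).
#'
#' @return A 15 x 2 matrix with rows named by parameter and columns
#'   `lo`, `hi`.
#' @export
default_intervals <- function() {
  m <- rbind(
    alpha   = c(1.521, 1.848),
    phi     = c(0.0072, 0.0088),
    beta    = c(0.00027, 0.00033),
    epsilon = c(0.00072, 0.00088),
    eta     = c(0.0000009, 0.0000011),
    p       = c(0.0144, 0.0176),
    mu      = c(0.019305, 0.023595),
    omega   = c(0.055197, 0.067463),
    K       = c(10000, 12000),
    theta   = c(0.00036, 0.00044),
    sigma   = c(0.009, 0.011),
    s       = c(0.004761, 0.005819),
    M       = c(1542, 1892),
    nu      = c(0.0009, 0.0011),
    pi      = c(0.000045, 0.000055)
  )
  colnames(m) <- c("lo", "hi")
  m
}

# Validate a 4-state vector; returns named numeric c(C, G, F, N).
as_state <- function(state) {
  state <- unlist(state)
  if (length(state) != 4L) {
    stop("state must have 4 components (C, G, F, N)", call. = FALSE)
  }
  nm <- c("C", "G", "F", "N")
  if (!is.null(names(state)) && all(nm %in% names(state))) {
    state <- state[nm]
  } else {
    names(state) <- nm
  }
  if (any(!is.finite(state))) {
    stop("non-finite state component: ",
         paste(nm[!is.finite(state)], collapse = ", "), call. = FALSE)
  }
  state
}
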