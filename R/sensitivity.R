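#' Latin hypercube sample of the parameter space
#'
#' Stratified uniform sampling: for each parameter, the `n` draws occupy
#' `n` distinct equal-probability strata of its `[lo, hi]` interval
#' (one draw per stratum), then strata are randomly paired across
#' parameters. Bit-reproducible under a fixed seed.
#'
#' @param n number of samples (>= 10 recommended for PRCC work).
#' @param intervals per-parameter `[lo, hi]` matrix as from
#'   [default_intervals()]; rows named by parameter.
#' @param seed integer RNG seed.
#' @return An `n x k` matrix with columns named by parameter; attribute
#'   `design` records `n`, `intervals` and `seed`.
#' @export
lhs_sample <- function(n, intervals = default_intervals(), seed = 1L) {
  stopifnot(is.matrix(intervals), ncol(intervals) == 2,
            !is.null(rownames(intervals)))
  bad <- rownames(intervals)[intervals[, 1] >= intervals[, 2]]
  if (length(bad) > 0) {
    stop("interval with lo >= hi for parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  k <- nrow(intervals)
  u <- local_seed(seed, lhs::randomLHS(n, k))
  x <- sweep(u, 2, intervals[, 2] - intervals[, 1], `*`)
  x <- sweep(x, 2, intervals[, 1], `+`)
  colnames(x) <- rownames(intervals)
  attr(x, "design") <- list(n = n, intervals = intervals, seed = seed)
  x
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Partial rank correlation coefficients
#'
#' For each input column `i`: rank-transform every column (average ranks
#' for ties), regress both `rank(X_i)` and `rank(Y)` on the ranks of the
#' remaining inputs (with intercept), and take the product-moment
#' correlation of the two residual vectors. This is the standard PRCC:
#' monotone sensitivity of the output to each parameter, controlling for
#' co-varying parameters.
#'
#' @param X numeric sample matrix (rows = model runs, columns = inputs).
#' @param y numeric output vector, one value per run.
#' @param pvalues also return two-sided p-values from the t statistic with
#'   `n - 2 - (k - 1)` degrees of freedom (raw, unadjusted).
#' @return Named vector of coefficients in `[-1, 1]` (or a data frame with
#'   columns `parameter`, `prcc`, `p.value` when `pvalues = TRUE`). A
#'   constant output yields `NA` coefficients with a warning.
#' @export
prcc <- function(X, y, pvalues = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= k + 2) stop("need more runs than inputs + 2 for PRCC",
                       call. = FALSE)
  if (stats::sd(y) == 0) {
    warning("constant output vector: PRCC undefined")
    out <- stats::setNames(rep(NA_real_, k), colnames(X))
    if (pvalues) {
      return(data.frame(parameter = colnames(X), prcc = out,
                        p.value = NA_real_, row.names = NULL))
    }
    return(out)
  }
  R <- apply(X, 2, rank, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  coefs <- vapply(seq_len(k), function(i) {
    Z <- cbind(1, R[, -i, drop = FALSE])
    qz <- qr(Z)
    ex <- qr.resid(qz, R[, i])
    ey <- qr.resid(qz, ry)
    if (stats::sd(ex) == 0 || stats::sd(ey) == 0) return(NA_real_)
    stats::cor(ex, ey)
  }, numeric(1))
  names(coefs) <- colnames(X)
  if (!pvalues) return(coefs)
  df <- n - 2 - (k - 1)
  tstat <- coefs * sqrt(df / pmax(1 - coefs^2, .Machine$double.eps))
  data.frame(parameter = colnames(X), prcc = coefs,
             p.value = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
             row.names = NULL)
}

#' Time-resolved PRCC of the model outputs
#'
#' Draws a Latin hypercube sample of the full parameter space, integrates
#' the model once per sample row from a common initial state, records the
#' four compartments at each requested time, and computes PRCC per output
#' and time point. Failed integrations are excluded and counted; more
#' than 1 percent failures aborts (the design is likely infeasible).
#'
#' @param n sample size (1000 reproduces typical published designs; 300 is
#'   adequate for sign and ranking questions).
#' @param intervals sampling intervals as in [lhs_sample()].
#' @param init common initial state for all runs.
#' @param t_points times (years, in `(0, 4000]`-ish) at which outputs are
#'   recorded.
#' @param seed RNG seed for the hypercube.
#' @param rtol,atol solver tolerances for the batch integrations.
#' @return A long data frame `parameter, output, t, prcc` of class
#'   `carbo_prcc`, with attributes `n_failed` and `design`.
#' @export
prcc_over_time <- function(n = 1000, intervals = default_intervals(),
                           init = c(C = 130, G = 0.121, F = 1003, N = 80),
                           t_points = 4000, seed = 1L,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(all(t_points > 0))
  X <- lhs_sample(n, intervals, seed)
  t_points <- sort(unique(as.numeric(t_points)))
  times <- c(0, t_points)
  outputs <- c("C", "G", "F", "N")
  res <- array(NA_real_, dim = c(n, length(t_points), 4),
               dimnames = list(NULL, as.character(t_points), outputs))
  ok <- logical(n)
  for (i in seq_len(n)) {
    pars <- try(as_carbo_params(X[i, ]), silent = TRUE)
    tr <- if (inherits(pars, "try-error")) pars else
      try(suppressWarnings(simulate_model(pars, init, times,
                                          rtol = rtol, atol = atol)),
          silent = TRUE)
    if (!inherits(tr, "try-error")) {
      m <- as.matrix(tr[match(t_points, tr$t), outputs])
      if (all(is.finite(m))) {
        res[i, , ] <- m
        ok[i] <- TRUE
      }
    }
  }
  n_failed <- sum(!ok)
  if (n_failed > 0.01 * n) {
    stop(sprintf("%d of %d integrations failed (> 1%%): design infeasible",
                 n_failed, n), call. = FALSE)
  }
  Xok <- X[ok, , drop = FALSE]
  rows <- list()
  for (j in seq_along(t_points)) {
    for (v in outputs) {
      cf <- prcc(Xok, res[ok, j, v])
      rows[[length(rows) + 1]] <- data.frame(
        parameter = names(cf), output = v, t = t_points[j], prcc = cf,
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("carbo_prcc", "data.frame"),
            n_failed = n_failed, design = attr(X, "design"))
}
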