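#' Fit an exponential memory decay
#'
#' Unweighted nonlinear least squares of `A exp(-lambda g)` to a correlation
#' (or variance) series over `g` in `[0, g_max]`, with the constraint
#' `lambda >= 0`. The memory half-life is `ln 2 / lambda`; a fitted rate
#' below `1e-6` is reported as non-decaying (`half_life = Inf`).
#'
#' @param grid Grid values (generations or minutes).
#' @param values Series values at `grid`.
#' @param g_max Fit range: points with `grid <= g_max` are used (default 10).
#' @return List with `A`, `lambda` (per grid unit), `half_life`, `n_points`,
#'   `residuals`.
#' @examples
#' g <- 0:10
#' fit_exponential(g, exp(-log(2) / 4.5 * g))$half_life
#' @export
fit_exponential <- function(grid, values, g_max = 10) {
  ok <- is.finite(grid) & is.finite(values) & grid <= g_max + 1e-9
  g <- grid[ok]
  y <- values[ok]
  if (length(g) < 4) {
    stop("fit_exponential: need at least 4 grid points within the fit range",
         call. = FALSE)
  }
  if (stats::sd(y) < 1e-12) {
    # constant series: non-decaying by definition
    return(list(A = mean(y), lambda = 0, half_life = Inf,
                n_points = length(g), residuals = y - mean(y)))
  }
  # starting values from a log-linear regression on the positive part
  pos <- y > 0
  if (sum(pos) >= 2 && stats::var(g[pos]) > 0) {
    cf <- stats::coef(stats::lm(log(y[pos]) ~ g[pos]))
    A0 <- min(max(exp(cf[1]), 1e-8), 10 * max(abs(y)))
    l0 <- max(-cf[2], 0)
  } else {
    A0 <- max(y)
    l0 <- 0.1
  }
  dat <- data.frame(g = g, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-lambda * g), data = dat,
                      start = list(A = A0, lambda = max(l0, 1e-4)),
                      lower = c(A = -Inf, lambda = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    cond <- simpleError(paste0("fit_exponential: fit failed: ",
                               conditionMessage(fit)))
    cond$residuals <- y - A0 * exp(-l0 * g)
    stop(cond)
  }
  co <- stats::coef(fit)
  lambda <- unname(co["lambda"])
  list(A = unname(co["A"]),
       lambda = lambda,
       half_life = if (lambda < 1e-6) Inf else log(2) / lambda,
       n_points = length(g),
       residuals = unname(stats::residuals(fit)))
}
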