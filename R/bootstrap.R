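#' Bootstrap standard errors of a pair-ensemble statistic
#'
#' Resamples pairs with replacement (seeded), recomputes the statistic and
#' returns the per-component standard deviation across replicates — the
#' shaded-error convention used for correlation and variance series.
#' Deterministic given `seed`, and the caller's RNG state is left untouched.
#'
#' @param statistic Function taking a `pair_ensemble` and returning a numeric
#'   vector (scalar statistics return length 1).
#' @param ensemble A `pair_ensemble`.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed RNG seed for the resampling.
#' @return Numeric vector of standard errors, one per statistic component.
#' @export
bootstrap_se <- function(statistic, ensemble, n_boot = 1000, seed = 1) {
  n <- ensemble$n
  if (n < 3) stop("bootstrap_se: need at least 3 pairs", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  draws <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  reps <- lapply(seq_len(n_boot), function(b) {
    statistic(subset_pairs(ensemble, draws[b, ]))
  })
  lens <- vapply(reps, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("bootstrap_se: statistic returned vectors of differing length",
         call. = FALSE)
  }
  m <- do.call(rbind, reps)
  apply(m, 2, stats::sd, na.rm = TRUE)
}
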