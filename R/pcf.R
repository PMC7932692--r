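#' Pair Pearson correlation at one generation
#'
#' The pair correlation function (PCF) at generation `g` is the Pearson
#' correlation, across the ensemble's pairs, of the property's values in the
#' two members' `g`-th post-alignment cycles. Because pair members are
#' unordered, the estimator is symmetrized over the two orderings (each pair
#' contributes `(a, b)` and `(b, a)`), with the mean and the population
#' (1/n) variance taken over the pooled contributing values:
#' `PCF = mean((a - m)(b - m)) / v`.
#'
#' By the alignment convention, the value at `g = 0` (the alignment origin,
#' where sister cells have just separated and neighbor/random pairs are
#' defined to coincide) is exactly 1; measured generations start at `g = 1`,
#' each pair's first full post-alignment cycle.
#'
#' @param ensemble A `pair_ensemble`.
#' @param property Per-cycle property: `"T"`, `"L_birth"`, `"L_div"`,
#'   `"alpha_cycle"` or `"f_mean"`.
#' @param g Generation index (0-based grid; `g = 0` returns 1 by convention).
#' @param min_pairs Minimum complete pairs required (default 3).
#' @return Correlation in `[-1, 1]`.
#' @export
pcf <- function(ensemble, property = "T", g, min_pairs = 3) {
  if (g == 0) return(1)
  m <- pair_gen_property(ensemble, property, g)
  ok <- stats::complete.cases(m)
  if (sum(ok) < min_pairs) {
    stop("pcf: fewer than ", min_pairs, " complete pairs at generation ", g,
         call. = FALSE)
  }
  symmetrized_pearson(m[ok, 1], m[ok, 2])
}

# Symmetrized (intraclass-style) Pearson correlation with population
# normalization; errors on zero variance (degenerate, e.g. noise-free data).
symmetrized_pearson <- function(a, b) {
  pool <- c(a, b)
  mu <- mean(pool)
  v <- mean((pool - mu)^2)
  if (v <= .Machine$double.eps * max(1, mu^2)) {
    stop("degenerate input: zero variance across pairs", call. = FALSE)
  }
  r <- mean((a - mu) * (b - mu)) / v
  min(1, max(-1, r))
}

#' PCF series over generations, with bootstrap errors and decay fit
#'
#' Evaluates [pcf()] on the generation grid `0..g_max` (the origin carries the
#' conventional value 1), attaches bootstrap standard errors from resampling
#' pairs, and fits the single-exponential memory decay `A exp(-lambda g)`
#' whose half-life `ln 2 / lambda` summarizes the ensemble's memory.
#'
#' @param ensemble A `pair_ensemble`.
#' @param property Per-cycle property (see [pcf()]).
#' @param g_max Last generation of the grid (default 10).
#' @param n_boot Bootstrap replicates for standard errors (default 200).
#' @param seed Seed for the bootstrap.
#' @param min_pairs Minimum pairs per grid point.
#' @return A `correlation_series`: list with `grid` (generations), `values`,
#'   `se`, `n_pairs`, `fit` (`A`, `lambda`, `half_life`), `grid_unit`,
#'   `property`, `pair_type`.
#' @export
pcf_by_generation <- function(ensemble, property = "T", g_max = 10,
                              n_boot = 200, seed = 1, min_pairs = 3) {
  gs <- 0:g_max
  mats <- lapply(gs[-1], function(g) pair_gen_property(ensemble, property, g))
  vals <- rep(NA_real_, length(gs))
  np <- integer(length(gs))
  vals[1] <- 1
  np[1] <- ensemble$n
  for (i in seq_along(gs)[-1]) {
    m <- mats[[i - 1]]
    ok <- stats::complete.cases(m)
    np[i] <- sum(ok)
    if (np[i] >= min_pairs) {
      vals[i] <- tryCatch(symmetrized_pearson(m[ok, 1], m[ok, 2]),
                          error = function(e) NA_real_)
    }
  }
  se <- rep(NA_real_, length(gs))
  if (n_boot >= 2) {
    # resample pairs with replacement over the precomputed value matrices
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    reps <- matrix(NA_real_, n_boot, length(gs))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ensemble$n, replace = TRUE)
      for (i in seq_along(gs)[-1]) {
        m <- mats[[i - 1]][idx, , drop = FALSE]
        ok <- stats::complete.cases(m)
        if (sum(ok) >= min_pairs) {
          reps[b, i] <- tryCatch(symmetrized_pearson(m[ok, 1], m[ok, 2]),
                                 error = function(e) NA_real_)
        }
      }
    }
    se <- apply(reps, 2, stats::sd, na.rm = TRUE)
    se[1] <- 0
  }
  keep <- !is.na(vals)
  fit <- tryCatch(fit_exponential(gs[keep], vals[keep], g_max = g_max),
                  error = function(e) NULL)
  structure(list(grid = gs, values = vals, se = se, n_pairs = np, fit = fit,
                 grid_unit = "generations", property = property,
                 pair_type = ensemble$pair_type),
            class = "correlation_series")
}

#' Time-resolved PCF of an instantaneous property
#'
#' Computes the across-pair symmetrized Pearson correlation of an
#' instantaneous observable (cell length or fluorescence) at every frame of
#' the pairs' shared relative time grid, then boxcar-averages over
#' `smooth_frames` consecutive frames. The origin (`t = 0`) carries the
#' conventional value 1 and is excluded from smoothing. An exponential decay
#' is fitted versus time; divide its half-life by the ensemble mean cycle
#' time to express memory in generations.
#'
#' @param ensemble A `pair_ensemble`.
#' @param property `"length"` or `"fluor"`.
#' @param smooth_frames Boxcar width in frames (default 6; 1 disables
#'   smoothing beyond the per-frame values).
#' @param t_max_min Grid end in minutes (default `10 x` the ensemble mean
#'   cycle time).
#' @param n_boot,seed Bootstrap settings for standard errors.
#' @param min_pairs Minimum pairs per frame.
#' @return A `correlation_series` with `grid` in minutes.
#' @export
pcf_time <- function(ensemble, property = c("length", "fluor"),
                     smooth_frames = 6, t_max_min = NULL, n_boot = 100,
                     seed = 1, min_pairs = 3) {
  property <- match.arg(property)
  cs <- ensemble$cs
  dt <- infer_dt(cs)
  if (is.null(t_max_min)) {
    t_max_min <- 10 * mean(cs$cycles$T, na.rm = TRUE)
  }
  k_max <- floor(t_max_min / dt)

  mats <- pair_time_matrices(ensemble, property, k_max, dt)
  raw <- per_frame_sym_pearson(mats$A, mats$B, min_pairs)
  sm <- boxcar(raw, smooth_frames)
  sm[1] <- 1  # conventional origin, kept out of the smoothing

  se <- rep(NA_real_, length(sm))
  if (n_boot >= 2) {
    # resample pairs with replacement over the precomputed frame matrices
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    reps <- matrix(NA_real_, n_boot, length(sm))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ensemble$n, replace = TRUE)
      r <- per_frame_sym_pearson(mats$A[idx, , drop = FALSE],
                                 mats$B[idx, , drop = FALSE], min_pairs)
      reps[b, ] <- boxcar(r, smooth_frames)
    }
    se <- apply(reps, 2, stats::sd, na.rm = TRUE)
    se[1] <- 0
  }

  grid <- (0:k_max) * dt
  keep <- !is.na(sm)
  fit <- tryCatch(fit_exponential(grid[keep], sm[keep], g_max = max(grid)),
                  error = function(e) NULL)
  structure(list(grid = grid, values = sm, se = se,
                 n_pairs = attr(raw, "n"), fit = fit, grid_unit = "minutes",
                 property = property, pair_type = ensemble$pair_type),
            class = "correlation_series")
}

# pairs x frames matrices of an instantaneous property on the relative grid
pair_time_matrices <- function(ensemble, property, k_max, dt) {
  cs <- ensemble$cs
  cy <- cs$cycles
  fr <- cs$frames[!is.na(cs$frames$cycle_id), , drop = FALSE]
  val <- if (property == "length") fr$length else fr$fluor
  gen <- cy$gen[match(fr$cycle_id, cy$cell_id)]
  p <- ensemble$pairs
  n <- nrow(p)
  A <- matrix(NA_real_, n, k_max + 1)
  B <- matrix(NA_real_, n, k_max + 1)
  by_lin <- split(data.frame(time_min = fr$time_min, gen = gen, val = val),
                  fr$lineage_id)
  fill <- function(M, lin, g0, t0) {
    for (i in seq_len(n)) {
      s <- by_lin[[lin[i]]]
      if (is.null(s)) next
      keep <- s$gen >= g0[i]
      k <- as.integer(round((s$time_min[keep] - t0[i]) / dt))
      v <- s$val[keep]
      ok <- k >= 0 & k <= k_max
      M[i, k[ok] + 1L] <- v[ok]
    }
    M
  }
  A <- fill(A, p$lineage_a, p$g0_a, p$t0_a)
  B <- fill(B, p$lineage_b, p$g0_b, p$t0_b)
  list(A = A, B = B)
}

# symmetrized Pearson per column (vectorized over the frame grid);
# NA where fewer than min_pairs complete pairs or the variance degenerates
per_frame_sym_pearson <- function(A, B, min_pairs) {
  miss <- is.na(A) | is.na(B)
  A[miss] <- NA
  B[miss] <- NA
  nn <- colSums(!miss)
  sa <- colSums(A, na.rm = TRUE)
  sb <- colSums(B, na.rm = TRUE)
  saa <- colSums(A^2, na.rm = TRUE)
  sbb <- colSums(B^2, na.rm = TRUE)
  sab <- colSums(A * B, na.rm = TRUE)
  mu <- (sa + sb) / (2 * nn)
  v <- (saa + sbb) / (2 * nn) - mu^2
  cv <- sab / nn - mu * (sa + sb) / nn + mu^2
  out <- pmin(1, pmax(-1, cv / v))
  bad <- nn < min_pairs | !is.finite(out) |
    v <= .Machine$double.eps * pmax(1, mu^2)
  out[bad] <- NA_real_
  attr(out, "n") <- nn
  out
}

# centered boxcar mean over available (non-NA) neighbors
boxcar <- function(x, width) {
  if (width <= 1) return(x)
  h <- floor(width / 2)
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- max(1, i - h):min(n, i + h)
    v <- x[j]
    if (any(!is.na(v))) out[i] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Lineage autocorrelation of a per-generation property
#'
#' Lag-`g` Pearson autocorrelation of a per-cycle property along single
#' lineages, pooled across lineages (pooled means and population SDs over all
#' contributing value pairs). Contrast with the pair correlation function:
#' the ACF follows one lineage in time, so trap-to-trap diversity of the
#' property enters its normalization.
#'
#' @param cs A `cycle_set`.
#' @param property Per-cycle property name.
#' @param lags Integer lags in generations (default `0:10`).
#' @param by_trap If `TRUE`, return one ACF per trap (a named list).
#' @return A `correlation_series` on the lag grid (or a list of them).
#' @export
acf_lineage <- function(cs, property = "T", lags = 0:10, by_trap = FALSE) {
  cy <- cs$cycles[!is.na(cs$cycles$lineage_id), , drop = FALSE]
  if (by_trap) {
    traps <- split(cy, cy$trap_id)
    return(lapply(traps, function(sub) {
      acf_pooled(sub, property, lags)
    }))
  }
  acf_pooled(cy, property, lags)
}

acf_pooled <- function(cy, property, lags) {
  vals <- rep(NA_real_, length(lags))
  npt <- integer(length(lags))
  for (i in seq_along(lags)) {
    lag <- lags[i]
    xs <- ys <- numeric(0)
    for (lin in unique(cy$lineage_id)) {
      sub <- cy[cy$lineage_id == lin, , drop = FALSE]
      sub <- sub[order(sub$gen), , drop = FALSE]
      y <- sub[[property]]
      n <- length(y)
      if (n > lag) {
        xs <- c(xs, y[seq_len(n - lag)])
        ys <- c(ys, y[seq_len(n - lag) + lag])
      }
    }
    npt[i] <- length(xs)
    if (length(xs) >= 3) {
      pool <- c(xs, ys)
      mu <- mean(pool)
      v <- mean((pool - mu)^2)
      if (v <= .Machine$double.eps * max(1, mu^2)) {
        stop("acf_lineage: degenerate input, zero variance", call. = FALSE)
      }
      vals[i] <- min(1, max(-1, mean((xs - mu) * (ys - mu)) / v))
    }
  }
  structure(list(grid = lags, values = vals, se = rep(NA_real_, length(lags)),
                 n_pairs = npt, fit = NULL, grid_unit = "generations",
                 property = property, pair_type = "ACF"),
            class = "correlation_series")
}

#' @export
print.correlation_series <- function(x, ...) {
  cat(sprintf("<correlation_series> %s of %s on %s grid (%d points)\n",
              x$pair_type, x$property, x$grid_unit, length(x$grid)))
  if (!is.null(x$fit)) {
    cat(sprintf("  fit: A = %.3f, lambda = %.4f per %s, half-life = %.3g %s\n",
                x$fit$A, x$fit$lambda, sub("s$", "", x$grid_unit),
                x$fit$half_life, x$grid_unit))
  }
  invisible(x)
}

#' @export
as.data.frame.correlation_series <- function(x, ...) {
  data.frame(grid = x$grid, value = x$values, se = x$se, n = x$n_pairs)
}
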