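#' Across-pair variance dynamics of a difference series
#'
#' At each point of the shared relative time grid, the population variance of
#' the pair differences `delta y(t)` across all contributing pairs, then a
#' centered boxcar average over `smooth_frames` consecutive frames. Two
#' saturation metrics summarize the approach to equilibrium:
#' `saturation_value`, the mean over the final `plateau_frac` of the grid,
#' and `saturation_time_min`, the first grid time from which the series stays
#' within `band` (relative) of the saturation value.
#'
#' @param ds A `delta_series` from [delta_series()].
#' @param smooth_frames Boxcar width in frames (default 3).
#' @param min_pairs Minimum contributing pairs per grid point (default 3);
#'   sparser points become gaps.
#' @param plateau_frac Fraction of the grid tail defining the plateau
#'   (default 0.25).
#' @param band Relative band around the plateau defining saturation
#'   (default 0.10).
#' @param sat_smooth_frames Boxcar width used only for the saturation
#'   metrics (default: same as `smooth_frames`). A wider window keeps the
#'   band test from being dominated by per-point sampling noise.
#' @return An object of class `variance_series`: `grid` (minutes), `var`
#'   (smoothed), `var_raw`, `n`, `smooth_window`, `saturation_value`,
#'   `saturation_time_min`.
#' @export
variance_series <- function(ds, smooth_frames = 3, min_pairs = 3,
                            plateau_frac = 0.25, band = 0.10,
                            sat_smooth_frames = smooth_frames) {
  stopifnot(inherits(ds, "delta_series"))
  d <- ds$deltas[!is.na(ds$deltas$delta), , drop = FALSE]
  grid <- sort(unique(ds$deltas$t))
  idx <- split(d$delta, factor(d$t, levels = grid))
  n <- lengths(idx)
  v <- vapply(idx, function(x) {
    if (length(x) < min_pairs) NA_real_ else mean((x - mean(x))^2)
  }, numeric(1))
  names(v) <- NULL
  n <- unname(n)
  sm <- boxcar(v, smooth_frames)
  mets <- saturation_metrics(grid, boxcar(v, sat_smooth_frames),
                             plateau_frac, band)
  structure(list(grid = grid, var = sm, var_raw = v, n = n,
                 smooth_window = smooth_frames,
                 saturation_value = mets$value,
                 saturation_time_min = mets$time,
                 grid_unit = "minutes"),
            class = "variance_series")
}

# plateau = mean of the final plateau_frac of the (smoothed) series;
# saturation time = first grid point from which the series stays inside
# plateau * (1 +/- band) for a persistence horizon as long as the plateau
# window itself (demanding the band hold to the grid end would let a single
# late sampling-noise excursion dominate the metric).
saturation_metrics <- function(grid, v, plateau_frac = 0.25, band = 0.10) {
  ok <- which(!is.na(v))
  if (!length(ok)) return(list(value = NA_real_, time = NA_real_))
  tail_start <- ok[ok >= stats::quantile(ok, 1 - plateau_frac, type = 1)]
  value <- mean(v[tail_start])
  inside <- abs(v - value) <= band * abs(value) | is.na(v)
  persist <- max(1L, length(tail_start))
  t_sat <- NA_real_
  for (i in seq_along(grid)) {
    if (is.na(v[i])) next
    horizon <- i:min(length(grid), i + persist - 1L)
    if (all(inside[horizon])) { t_sat <- grid[i]; break }
  }
  list(value = value, time = t_sat)
}

#' @export
print.variance_series <- function(x, ...) {
  cat(sprintf("<variance_series> %d points on %s grid; plateau %.4g, saturation at %.4g %s\n",
              length(x$grid), x$grid_unit, x$saturation_value,
              if (x$grid_unit == "minutes") x$saturation_time_min else x$saturation_time,
              x$grid_unit))
  invisible(x)
}

#' Saturating-exponential fit to a rising variance series
#'
#' For variance dynamics that rise monotonically to an equilibrium plateau
#' (e.g. the fluorescence difference of sister pairs, whose population
#' variance follows `2 sigma^2 (1 - exp(-2 t / tau))` for independent OU
#' members started equal), fits `V (1 - exp(-t / tau_eff))` by nonlinear
#' least squares and reports the fitted 90%-of-plateau crossing time
#' `tau_eff ln 10`. The fit pools the whole series, so the crossing estimate
#' is far less sensitive to per-point sampling noise than band-entry on the
#' raw curve.
#'
#' @param vs A `variance_series`.
#' @return List with `V` (plateau), `tau_eff`, `t90` (grid units).
#' @export
fit_saturation <- function(vs) {
  ok <- !is.na(vs$var)
  g <- vs$grid[ok]
  y <- vs$var[ok]
  if (length(g) < 4) stop("fit_saturation: need at least 4 points", call. = FALSE)
  V0 <- max(stats::median(utils::tail(y, ceiling(length(y) / 4))), 1e-12)
  tau0 <- max(diff(range(g)) / 5, 1e-6)
  fit <- minpack.lm::nlsLM(y ~ V * (1 - exp(-g / tau)),
                           data = data.frame(g = g, y = y),
                           start = list(V = V0, tau = tau0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  if (!is.finite(co["V"]) || !is.finite(co["tau"]) || co["V"] <= 0 ||
      co["tau"] <= 0) {
    stop("fit_saturation: fit did not converge to a rising-saturation curve",
         call. = FALSE)
  }
  list(V = unname(co["V"]), tau_eff = unname(co["tau"]),
       t90 = unname(co["tau"]) * log(10))
}

#' Across-pair variance of per-generation property differences
#'
#' The analogue of [variance_series()] on the generation grid: variance over
#' pairs of `y_a(g) - y_b(g)` for a per-cycle property, with the same
#' saturation metrics. For sister pairs the variance grows from its
#' post-division value to an equilibrium plateau as the shared inherited
#' state decorrelates; for neighbor/random pairs it is flat.
#'
#' @param ensemble A `pair_ensemble`.
#' @param property `"T"` or `"L_birth"` (any per-cycle column works).
#' @param g_max Last generation (default 10).
#' @param min_pairs Minimum pairs per generation.
#' @param plateau_frac,band Saturation metric parameters, as in
#'   [variance_series()].
#' @return A `variance_series` with `grid` in generations (and
#'   `saturation_time` in generations).
#' @export
variance_by_generation <- function(ensemble, property = "T", g_max = 10,
                                   min_pairs = 3, plateau_frac = 0.25,
                                   band = 0.10) {
  gs <- 1:g_max
  v <- rep(NA_real_, length(gs))
  n <- integer(length(gs))
  for (i in seq_along(gs)) {
    m <- pair_gen_property(ensemble, property, gs[i])
    ok <- stats::complete.cases(m)
    n[i] <- sum(ok)
    if (n[i] >= min_pairs) {
      d <- m[ok, 1] - m[ok, 2]
      v[i] <- mean((d - mean(d))^2)
    }
  }
  mets <- saturation_metrics(gs, v, plateau_frac, band)
  structure(list(grid = gs, var = v, var_raw = v, n = n, smooth_window = 1,
                 saturation_value = mets$value, saturation_time = mets$time,
                 grid_unit = "generations"),
            class = "variance_series")
}

#' Average growth-rate differences of sister versus random pairs
#'
#' For each pair with at least `min_cycles` common post-alignment
#' generations, the absolute difference of the members' mean per-cycle
#' elongation rates. Reports the per-type spreads `sd_sc` and `sd_rp`
#' (computed as the root mean square of the absolute differences, i.e. the
#' population SD of the signed difference, which is symmetric about zero)
#' and their ratio. A ratio well below 1 indicates that co-trapped sisters
#' share a growth environment (micro-niche) and inherited growth state that
#' random cross-trap pairs do not.
#'
#' @param sc A sister-pair ensemble.
#' @param rp A random-pair ensemble.
#' @param min_cycles Minimum common full cycles per pair (default 5).
#' @return A `pair_difference_summary`: list with `samples_sc`, `samples_rp`
#'   (absolute differences, 1/min), `sd_sc`, `sd_rp`, `ratio`.
#' @export
pair_rate_difference_summary <- function(sc, rp, min_cycles = 5) {
  grab <- function(ens) {
    if (ens$n == 0) return(numeric(0))
    g_max <- max(table(ens$cs$cycles$lineage_id))
    A <- B <- matrix(NA_real_, ens$n, g_max)
    for (g in seq_len(g_max)) {
      m <- pair_gen_property(ens, "alpha_cycle", g)
      A[, g] <- m[, 1]
      B[, g] <- m[, 2]
    }
    ok <- !is.na(A) & !is.na(B)
    out <- numeric(0)
    for (i in seq_len(ens$n)) {
      # leading run of generations where both members have full cycles
      run <- which(!ok[i, ])
      n_common <- if (length(run)) run[1] - 1L else g_max
      if (n_common >= min_cycles) {
        idx <- seq_len(n_common)
        out <- c(out, abs(mean(A[i, idx]) - mean(B[i, idx])))
      }
    }
    out
  }
  s_sc <- grab(sc)
  s_rp <- grab(rp)
  if (!length(s_sc) || !length(s_rp)) {
    stop("pair_rate_difference_summary: no pairs with >= ", min_cycles,
         " common cycles", call. = FALSE)
  }
  rms <- function(x) sqrt(mean(x^2))
  structure(list(samples_sc = s_sc, samples_rp = s_rp,
                 sd_sc = rms(s_sc), sd_rp = rms(s_rp),
                 ratio = rms(s_sc) / rms(s_rp)),
            class = "pair_difference_summary")
}

#' @export
print.pair_difference_summary <- function(x, ...) {
  cat(sprintf("<pair_difference_summary> sd_SC %.4g, sd_RP %.4g, ratio %.3f (n = %d / %d)\n",
              x$sd_sc, x$sd_rp, x$ratio, length(x$samples_sc),
              length(x$samples_rp)))
  invisible(x)
}
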