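#' Windowed instantaneous elongation rate
#'
#' Estimates `alpha(t) = d ln L / dt` over a short moving time window within
#' each cell cycle: at every frame whose full window lies inside the cycle,
#' the least-squares slope of `ln(length)` versus time over the frames within
#' `window_min / 2` of the center. Windows that would cross a division are
#' skipped, so the trace has gaps of half a window around each division.
#'
#' With the default 6-min window at a 3-min cadence each estimate uses 3
#' frames.
#'
#' @param cs A `cycle_set`.
#' @param window_min Window width in minutes (default 6).
#' @return `data.frame` with `lineage_id`, `cycle_id`, `time_min`, `alpha`
#'   (1/min), one row per admissible window center.
#' @export
windowed_alpha <- function(cs, window_min = 6) {
  fr <- cs$frames
  if (!nrow(fr)) {
    return(data.frame(lineage_id = character(), cycle_id = character(),
                      time_min = numeric(), alpha = numeric()))
  }
  dt <- infer_dt(cs)
  h <- floor(window_min / (2 * dt))
  if (h < 1) {
    stop("windowed_alpha: window of ", window_min,
         " min spans fewer than 2 frames at a ", dt, "-min cadence",
         call. = FALSE)
  }
  m <- -h:h
  w <- m / (dt * sum(m^2))  # closed-form least-squares slope weights
  fcoef <- rev(w)           # stats::filter convolution reverses coefficients

  fr <- fr[!is.na(fr$cycle_id), , drop = FALSE]
  o <- order(fr$cycle_id, fr$frame)
  fr <- fr[o, , drop = FALSE]
  idx <- split(seq_len(nrow(fr)), fr$cycle_id)
  out <- lapply(idx, function(ii) {
    n <- length(ii)
    if (n < 2 * h + 1) return(NULL)
    x <- log(fr$length[ii])
    a <- as.numeric(stats::filter(x, fcoef, method = "convolution", sides = 2))
    keep <- which(!is.na(a))
    data.frame(lineage_id = fr$lineage_id[ii[keep]],
               cycle_id = fr$cycle_id[ii[keep]],
               time_min = fr$time_min[ii[keep]],
               alpha = a[keep], stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(lineage_id = character(), cycle_id = character(),
                      time_min = numeric(), alpha = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-pair difference series of elongation rate or fluorescence
#'
#' Computes the signed difference `delta y(t) = y_a(t) - y_b(t)` between the
#' two members of every pair, on each pair's shared relative time grid
#' (member order fixed by the pair manifest, so ensemble averages of the
#' signed delta are meaningful). For `property = "alpha"` the members'
#' 6-min windowed elongation rates are used; for `"fluor"` the per-frame
#' concentrations. A pair contributes at a grid point only where both members
#' are observed.
#'
#' @param ensemble A `pair_ensemble`.
#' @param property `"alpha"` or `"fluor"`.
#' @param window_min Window for [windowed_alpha()] (minutes).
#' @param t_max_min Optional truncation of the relative time grid.
#' @param alpha_trace Optional precomputed [windowed_alpha()] trace for the
#'   ensemble's `cycle_set` (avoids recomputation across ensembles).
#' @return An object of class `delta_series`: list with `property`, `dt`,
#'   `deltas` (long `data.frame`: `pair_id`, `t`, `delta`).
#' @export
delta_series <- function(ensemble, property = c("alpha", "fluor"),
                         window_min = 6, t_max_min = NULL,
                         alpha_trace = NULL) {
  property <- match.arg(property)
  cs <- ensemble$cs
  dt <- infer_dt(cs)
  cy <- cs$cycles

  if (property == "alpha") {
    tr <- if (is.null(alpha_trace)) windowed_alpha(cs, window_min) else
      alpha_trace
    names(tr)[names(tr) == "alpha"] <- "value"
  } else {
    fr <- cs$frames[!is.na(cs$frames$cycle_id), , drop = FALSE]
    tr <- data.frame(lineage_id = fr$lineage_id, cycle_id = fr$cycle_id,
                     time_min = fr$time_min, value = fr$fluor,
                     stringsAsFactors = FALSE)
  }
  # generation index of each trace point's cycle, for alignment trimming
  tr$gen <- cy$gen[match(tr$cycle_id, cy$cell_id)]

  p <- ensemble$pairs
  by_lineage <- split(tr[c("time_min", "value", "gen")], tr$lineage_id)
  member <- function(lin, g0, t0) {
    s <- by_lineage[[lin]]
    if (is.null(s)) return(list(k = integer(0), value = numeric(0)))
    keep <- s$gen >= g0
    k <- as.integer(round((s$time_min[keep] - t0) / dt))
    val <- s$value[keep]
    ok <- k >= 0 & !is.na(val)
    list(k = k[ok], value = val[ok])
  }
  rows <- lapply(seq_len(nrow(p)), function(i) {
    a <- member(p$lineage_a[i], p$g0_a[i], p$t0_a[i])
    b <- member(p$lineage_b[i], p$g0_b[i], p$t0_b[i])
    k <- intersect(a$k, b$k)
    if (!length(k)) return(NULL)
    d <- a$value[match(k, a$k)] - b$value[match(k, b$k)]
    data.frame(pair_id = p$pair_id[i], t = k * dt, delta = d,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  deltas <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(), t = numeric(), delta = numeric())
  rownames(deltas) <- NULL
  if (!is.null(t_max_min)) deltas <- deltas[deltas$t <= t_max_min, , drop = FALSE]
  structure(list(property = property, dt = dt, deltas = deltas),
            class = "delta_series")
}

#' @export
print.delta_series <- function(x, ...) {
  cat(sprintf("<delta_series> property %s, %d pairs, %d points\n",
              x$property, length(unique(x$deltas$pair_id)), nrow(x$deltas)))
  invisible(x)
}
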