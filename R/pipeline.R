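#' Simulate a dataset and optionally write it to disk
#'
#' Thin orchestration over [simulate_experiment()]: validates the
#' configuration, simulates, and (optionally) writes the lineage TSV plus a
#' YAML echo of the configuration next to it for provenance.
#'
#' @param config A [sim_config()], a preset name (`"LB-default"`), or a path
#'   to a YAML config file.
#' @param out Optional output directory.
#' @param seed Optional seed overriding `config$seed`.
#' @return The lineage table, invisibly when `out` is given.
#' @export
run_simulate <- function(config = "LB-default", out = NULL, seed = NULL) {
  cfg <- resolve_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  tab <- simulate_experiment(cfg)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_lineage_table(tab, file.path(out, "lineages.tsv"))
    yaml::write_yaml(unclass(cfg), file.path(out, "sim_config.yaml"))
    return(invisible(tab))
  }
  tab
}

resolve_config <- function(config) {
  if (inherits(config, "sim_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    if (identical(config, "LB-default")) return(sim_config())
    if (file.exists(config)) return(read_sim_config(config))
    stop("run_simulate: unknown preset or missing config file: ", config,
         call. = FALSE)
  }
  if (is.list(config)) return(do.call(sim_config, config))
  stop("run_simulate: cannot interpret 'config'", call. = FALSE)
}

#' Full memory analysis of a lineage dataset
#'
#' Runs the complete pair-memory pipeline on a lineage table: cycle
#' segmentation, pair construction (all sister pairs; neighbor pairs with the
#' given tolerances; seeded random cross-trap pairs), cycle-time PCFs per
#' pair type with exponential half-life fits, the time-resolved sister size
#' PCF (6-frame smoothed, half-life converted to generations via the mean
#' cycle time), cycle-time and birth-length ACFs, windowed-elongation-rate
#' difference variance dynamics per pair type with saturation metrics, the
#' fluorescence-difference variance, per-generation difference variances, and
#' the sister-versus-random average-growth-rate difference summary.
#'
#' @param data A lineage table `data.frame` or a path to a lineage TSV.
#' @param out Optional output directory for the JSON results bundle and
#'   per-series TSVs.
#' @param nc_div_sync_tol,nc_len_tol_rel,nc_epoch_gens,nc_min_align_gen,nc_max_align_gen
#'   Neighbor-pair tolerances and alignment window (see [build_nc_pairs()]).
#' @param n_rp Number of random pairs (default 120).
#' @param g_max Fit range in generations (default 10).
#' @param window_min Elongation-rate window in minutes (default 6).
#' @param n_boot Bootstrap replicates for series errors (default 200).
#' @param seed Seed for random pairing and bootstraps (default 1).
#' @return A `results_bundle` list; see Details in the package vignette.
#' @export
run_analyze <- function(data, out = NULL, nc_div_sync_tol = 1,
                        nc_len_tol_rel = 0.05, nc_epoch_gens = 6,
                        nc_min_align_gen = 5, nc_max_align_gen = 13,
                        n_rp = 120, g_max = 10, window_min = 6,
                        n_boot = 200, seed = 1) {
  tab <- if (is.character(data)) read_lineage_table(data) else
    validate_lineage_table(data)
  cs <- segment_cycles(tab)
  if (!nrow(cs$cycles)) stop("run_analyze: no complete cycles in input",
                             call. = FALSE)
  mean_T <- mean(cs$cycles$T)
  sd_T <- stats::sd(cs$cycles$T)
  # images per generation: one frame interval per cadence step of the cycle
  frames_per_cycle <- mean(cs$cycles$n_frames - 1L)

  sc <- build_sc_pairs(cs)
  nc <- build_nc_pairs(cs, div_sync_tol = nc_div_sync_tol,
                       len_tol_rel = nc_len_tol_rel,
                       epoch_gens = nc_epoch_gens,
                       min_align_gen = nc_min_align_gen,
                       max_align_gen = nc_max_align_gen)
  rp <- build_rp_pairs(cs, n_pairs = min(n_rp, max_rp_pairs(cs)), seed = seed)
  if (nc$n == 0) {
    warning("run_analyze: no qualifying neighbor pairs; NC outputs empty")
  }

  pcf_T <- list(
    SC = pcf_by_generation(sc, "T", g_max = g_max, n_boot = n_boot, seed = seed),
    NC = if (nc$n >= 3) pcf_by_generation(nc, "T", g_max = g_max,
                                          n_boot = n_boot, seed = seed) else NULL,
    RP = pcf_by_generation(rp, "T", g_max = g_max, n_boot = n_boot, seed = seed)
  )
  size_sc <- pcf_time(sc, "length", smooth_frames = 6,
                      t_max_min = g_max * mean_T, n_boot = min(n_boot, 100),
                      seed = seed)
  size_half_life_gen <- if (!is.null(size_sc$fit)) {
    size_sc$fit$half_life / mean_T
  } else NA_real_

  acf_T <- tryCatch(acf_lineage(cs, "T", lags = 0:g_max),
                    error = function(e) {
                      warning("run_analyze: cycle-time ACF degenerate: ",
                              conditionMessage(e))
                      NULL
                    })
  acf_Lb <- tryCatch(acf_lineage(cs, "L_birth", lags = 0:g_max),
                     error = function(e) NULL)

  t_max <- g_max * mean_T
  wa <- windowed_alpha(cs, window_min)
  d_sc <- delta_series(sc, "alpha", window_min = window_min, t_max_min = t_max,
                       alpha_trace = wa)
  d_nc <- if (nc$n >= 3) delta_series(nc, "alpha", window_min = window_min,
                                      t_max_min = t_max, alpha_trace = wa)
          else NULL
  d_rp <- delta_series(rp, "alpha", window_min = window_min, t_max_min = t_max,
                       alpha_trace = wa)
  v_sc <- variance_series(d_sc)
  v_nc <- if (!is.null(d_nc)) variance_series(d_nc) else NULL
  v_rp <- variance_series(d_rp)
  dal <- dalpha_metrics(v_sc, v_nc, v_rp, mean_T)

  f_sc <- delta_series(sc, "fluor", t_max_min = t_max)
  vf_sc <- variance_series(f_sc, sat_smooth_frames = 9)
  # rise time from the pooled saturating-exponential fit (noise-robust)
  f_fit <- tryCatch(fit_saturation(vf_sc), error = function(e) NULL)
  dfluor_sat_gen <- if (!is.null(f_fit)) f_fit$t90 / mean_T else
    vf_sc$saturation_time_min / mean_T

  vg_T <- variance_by_generation(sc, "T", g_max = g_max)
  vg_Lb <- variance_by_generation(sc, "L_birth", g_max = g_max)

  fig2b <- tryCatch(pair_rate_difference_summary(sc, rp),
                    error = function(e) NULL)

  grand_mean_dalpha <- mean(c(d_sc$deltas$delta,
                              if (!is.null(d_nc)) d_nc$deltas$delta,
                              d_rp$deltas$delta), na.rm = TRUE)

  bundle <- list(
    provenance = list(package = "sistermem",
                      version = as.character(utils::packageVersion("sistermem")),
                      seed = seed, g_max = g_max, window_min = window_min,
                      nc_div_sync_tol = nc_div_sync_tol,
                      nc_len_tol_rel = nc_len_tol_rel,
                      nc_epoch_gens = nc_epoch_gens, n_boot = n_boot),
    counts = list(cycles = nrow(cs$cycles), sc_pairs = sc$n, nc_pairs = nc$n,
                  rp_pairs = rp$n),
    mean_T = mean_T, sd_T = sd_T, frames_per_cycle = frames_per_cycle,
    grand_mean_dalpha = grand_mean_dalpha,
    pcf_T = pcf_T,
    half_lives = list(
      T_SC = fit_half_life(pcf_T$SC),
      T_NC = fit_half_life(pcf_T$NC),
      T_RP = fit_half_life(pcf_T$RP),
      size_SC_gen = size_half_life_gen
    ),
    pcf_size_SC = size_sc,
    acf = list(T = acf_T, L_birth = acf_Lb),
    dalpha = c(list(SC = v_sc, NC = v_nc, RP = v_rp), dal),
    dfluor = list(SC = vf_sc, saturation_gen = dfluor_sat_gen),
    var_by_generation = list(T_SC = vg_T, L_birth_SC = vg_Lb),
    fig2b = fig2b
  )
  class(bundle) <- "results_bundle"
  if (!is.null(out)) write_results_bundle(bundle, out)
  bundle
}

max_rp_pairs <- function(cs) {
  lin <- unique(cs$cycles[!is.na(cs$cycles$lineage_id),
                          c("lineage_id", "trap_id")])
  tot <- choose(nrow(lin), 2)
  same <- sum(choose(table(lin$trap_id), 2))
  tot - same
}

fit_half_life <- function(series) {
  if (is.null(series) || is.null(series$fit)) return(NA_real_)
  series$fit$half_life
}

# Sister delta-alpha variance relative to the neighbor/random plateau:
# initial excess (%) and the time of the post-separation minimum.
dalpha_metrics <- function(v_sc, v_nc, v_rp, mean_T) {
  plateau_vals <- c(if (!is.null(v_nc)) v_nc$var, v_rp$var)
  plateau <- mean(plateau_vals, na.rm = TRUE)
  ok <- which(!is.na(v_sc$var))
  if (!length(ok) || !is.finite(plateau) || plateau <= 0) {
    return(list(sc_initial = NA_real_, plateau_ncrp = NA_real_,
                excess_pct = NA_real_, t_min_min = NA_real_))
  }
  sc0 <- v_sc$var[ok[1]]
  early <- ok[v_sc$grid[ok] <= 3 * mean_T]
  t_min <- v_sc$grid[early[which.min(v_sc$var[early])]]
  list(sc_initial = sc0, plateau_ncrp = plateau,
       excess_pct = 100 * (sc0 / plateau - 1),
       t_min_min = t_min)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>\n")
  cat(sprintf("  cycles %d; pairs SC %d / NC %d / RP %d\n",
              x$counts$cycles, x$counts$sc_pairs, x$counts$nc_pairs,
              x$counts$rp_pairs))
  cat(sprintf("  mean T %.2f min (sd %.2f), %.1f frames/cycle\n",
              x$mean_T, x$sd_T, x$frames_per_cycle))
  hl <- x$half_lives
  cat(sprintf("  T-PCF half-lives: SC %.2f, NC %.2f, RP %.2f gen; size SC %.2f gen\n",
              hl$T_SC, if (is.null(hl$T_NC)) NA else hl$T_NC, hl$T_RP,
              hl$size_SC_gen))
  cat(sprintf("  delta-alpha: SC initial excess %.1f%% over NC/RP plateau, minimum at %.0f min\n",
              x$dalpha$excess_pct, x$dalpha$t_min_min))
  cat(sprintf("  delta-f saturation %.2f generations\n", x$dfluor$saturation_gen))
  if (!is.null(x$fig2b)) {
    cat(sprintf("  |mean growth-rate difference|: sd_SC/sd_RP = %.3f\n",
                x$fig2b$ratio))
  }
  invisible(x)
}

# JSON + per-series TSV output
write_results_bundle <- function(bundle, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ser <- function(s) {
    if (is.null(s)) return(NULL)
    list(grid = s$grid, values = if (!is.null(s$values)) s$values else s$var,
         se = s$se, grid_unit = s$grid_unit,
         fit = if (!is.null(s$fit)) s$fit[c("A", "lambda", "half_life")],
         saturation_value = s$saturation_value,
         saturation_time = if (!is.null(s$saturation_time_min))
           s$saturation_time_min else s$saturation_time)
  }
  js <- list(
    provenance = bundle$provenance,
    counts = bundle$counts,
    mean_T = bundle$mean_T, sd_T = bundle$sd_T,
    frames_per_cycle = bundle$frames_per_cycle,
    grand_mean_dalpha = bundle$grand_mean_dalpha,
    half_lives = bundle$half_lives,
    dalpha = bundle$dalpha[c("sc_initial", "plateau_ncrp", "excess_pct",
                             "t_min_min")],
    dfluor_saturation_gen = bundle$dfluor$saturation_gen,
    fig2b = if (!is.null(bundle$fig2b))
      bundle$fig2b[c("sd_sc", "sd_rp", "ratio")],
    pcf_T = lapply(bundle$pcf_T, ser),
    pcf_size_SC = ser(bundle$pcf_size_SC),
    acf = lapply(bundle$acf, ser),
    dalpha_series = lapply(bundle$dalpha[c("SC", "NC", "RP")], ser),
    dfluor_SC = ser(bundle$dfluor$SC),
    var_by_generation = lapply(bundle$var_by_generation, ser)
  )
  jsonlite::write_json(js, file.path(out, "results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  dump_series <- function(s, name) {
    if (is.null(s)) return()
    df <- data.frame(grid = s$grid,
                     value = if (!is.null(s$values)) s$values else s$var,
                     se = if (!is.null(s$se)) s$se else NA)
    utils::write.table(df, file.path(out, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  dump_series(bundle$pcf_T$SC, "pcf_T_SC")
  dump_series(bundle$pcf_T$NC, "pcf_T_NC")
  dump_series(bundle$pcf_T$RP, "pcf_T_RP")
  dump_series(bundle$pcf_size_SC, "pcf_size_SC")
  dump_series(bundle$dalpha$SC, "var_dalpha_SC")
  dump_series(bundle$dalpha$NC, "var_dalpha_NC")
  dump_series(bundle$dalpha$RP, "var_dalpha_RP")
  dump_series(bundle$dfluor$SC, "var_dfluor_SC")
  invisible(out)
}

#' Coarse calibration of generator parameters against target statistics
#'
#' Grid search over selected `sim_config` fields minimizing the summed
#' relative error of measured summary statistics against targets. Supported
#' target names: `mean_T` (minutes), `cv_T`, `frames_per_cycle`,
#' `sc_t_half_life` (generations). Deterministic given `seed`.
#'
#' @param targets Named numeric vector of target values (at least one).
#' @param grid Named list of candidate values per `sim_config` field.
#' @param base A base [sim_config()] supplying all other fields.
#' @param seed Simulation seed used for every candidate.
#' @param out Optional path to write the selected preset as YAML.
#' @return List with `config` (best [sim_config()]), `achieved` (named
#'   statistics), `score`, `per_target` (relative errors and a `failed` flag
#'   at 10% relative error), and `grid_results`.
#' @export
run_calibrate <- function(targets, grid, base = sim_config(n_traps = 40,
                                                           n_generations = 12),
                          seed = 1, out = NULL) {
  if (length(targets) == 0 || is.null(names(targets))) {
    stop("run_calibrate: 'targets' must be a non-empty named vector",
         call. = FALSE)
  }
  supported <- c("mean_T", "cv_T", "frames_per_cycle", "sc_t_half_life")
  bad <- setdiff(names(targets), supported)
  if (length(bad)) {
    stop("run_calibrate: unsupported target(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(combos))
  scores <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    over <- as.list(combos[i, , drop = FALSE])
    cfg <- base
    for (f in names(over)) cfg[[f]] <- over[[f]]
    cfg$seed <- seed
    class(cfg) <- "sim_config"
    validate_sim_config(cfg)
    ach <- calibration_stats(cfg, names(targets))
    rel <- abs(ach[names(targets)] - targets) / abs(targets)
    scores[i] <- sum(rel)
    results[[i]] <- list(over = over, achieved = ach, rel = rel)
  }
  best <- which.min(scores)
  over <- results[[best]]$over
  cfg <- base
  for (f in names(over)) cfg[[f]] <- over[[f]]
  cfg$seed <- seed
  class(cfg) <- "sim_config"
  per_target <- data.frame(target = names(targets), value = unname(targets),
                           achieved = unname(results[[best]]$achieved[names(targets)]),
                           rel_error = unname(results[[best]]$rel),
                           failed = unname(results[[best]]$rel) > 0.10)
  if (!is.null(out)) yaml::write_yaml(unclass(cfg), out)
  list(config = cfg, achieved = results[[best]]$achieved,
       score = scores[best], per_target = per_target,
       grid_results = data.frame(combos, score = scores))
}

calibration_stats <- function(cfg, wanted) {
  tab <- simulate_experiment(cfg)
  cs <- segment_cycles(tab)
  res <- c(mean_T = mean(cs$cycles$T),
           cv_T = stats::sd(cs$cycles$T) / mean(cs$cycles$T),
           frames_per_cycle = mean(cs$cycles$n_frames),
           sc_t_half_life = NA_real_)
  if ("sc_t_half_life" %in% wanted) {
    sc <- build_sc_pairs(cs)
    if (sc$n >= 3) {
      ser <- pcf_by_generation(sc, "T", n_boot = 0, seed = cfg$seed)
      res["sc_t_half_life"] <- fit_half_life(ser)
    }
  }
  res
}
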