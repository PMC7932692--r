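# Fixtures built in code: tiny configurations, hand-built lineage tables and
# pair ensembles used across test files.

# small, fast simulation config
tiny_config <- function(..., seed = 1) {
  sim_config(n_traps = 6, n_generations = 6, seed = seed, ...)
}

# all stochastic terms off; only deterministic exponential growth + adder
noise_free_config <- function(..., seed = 1) {
  sim_config(sigma_delta_rel = 0, sigma_r = 0, sigma_hT = 0, sigma_hL = 0,
             sigma_xi = 0, sigma_env_static = 0, sigma_env_dyn = 0,
             sigma_f_intr = 0, sigma_meas_L = 0, sigma_meas_f = 0,
             kappa = 0, n_traps = 4, n_generations = 6, seed = seed, ...)
}

# a hand-built lineage table: one cell growing exponentially, sampled every
# dt minutes, optionally flagged as dividing on the last frame
exp_trace <- function(n = 12, alpha = 0.02, L0 = 2, dt = 3, cell = "t1:a0001",
                      trap = "t1", parent = "t1:m0000", frame0 = 0, t0 = 0,
                      fluor = 100, divide_last = TRUE) {
  tt <- seq(0, by = dt, length.out = n)
  data.frame(trap_id = trap, cell_id = cell, parent_id = parent,
             frame = frame0 + seq_len(n) - 1L, time_min = t0 + tt,
             length = L0 * exp(alpha * tt), fluor = fluor,
             division = c(rep(0L, n - 1), as.integer(divide_last)),
             stringsAsFactors = FALSE)
}

# chain several exponential cycles into one tip lineage; each daughter's
# first frame coincides in time with the mother's division frame, so the
# underlying growth law is continuous across the junction
exp_lineage <- function(n_cycles = 3, n = 8, alpha = 0.02, L0 = 2, dt = 3,
                        trap = "t1", side = "a") {
  out <- NULL
  parent <- sprintf("%s:m0000", trap)
  t0 <- 0; frame0 <- 0L
  for (k in seq_len(n_cycles)) {
    id <- sprintf("%s:%s%04d", trap, side, k)
    tr <- exp_trace(n = n, alpha = alpha, L0 = L0, dt = dt, cell = id,
                    trap = trap, parent = parent, frame0 = frame0, t0 = t0)
    out <- rbind(out, tr)
    parent <- id
    t0 <- t0 + (n - 1) * dt
    frame0 <- frame0 + n - 1L
    L0 <- tail(tr$length, 1) / 2
  }
  out
}

# build a pair_ensemble directly from per-generation property values:
# vals_a, vals_b are matrices (pairs x generations) of cycle-time values
hand_ensemble <- function(vals_a, vals_b, type = "SC") {
  n <- nrow(vals_a)
  gmax <- ncol(vals_a)
  mk_cycles <- function(vals, tag) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(cell_id = sprintf("%s%03d:g%d", tag, i, seq_len(gmax)),
                 trap_id = sprintf("trap%03d", i),
                 parent_id = "x", birth_time = (seq_len(gmax) - 1) * 30,
                 division_time = seq_len(gmax) * 30, T = vals[i, ],
                 L_birth = vals[i, ], L_div = 2 * vals[i, ],
                 alpha_cycle = vals[i, ], f_mean = vals[i, ],
                 n_frames = 10L,
                 lineage_id = sprintf("%s%03d", tag, i),
                 gen = seq_len(gmax), stringsAsFactors = FALSE)
    }))
  }
  cy <- rbind(mk_cycles(vals_a, "A"), mk_cycles(vals_b, "B"))
  cs <- structure(list(cycles = cy, frames = data.frame()), class = "cycle_set")
  pairs <- data.frame(pair_id = sprintf("P%03d", seq_len(n)),
                      lineage_a = sprintf("A%03d", seq_len(n)),
                      lineage_b = sprintf("B%03d", seq_len(n)),
                      g0_a = 1L, g0_b = 1L, t0_a = 0, t0_b = 0,
                      trap_a = "tA", trap_b = "tB", stringsAsFactors = FALSE)
  sistermem:::new_pair_ensemble(type, pairs, cs)
}

# direct arithmetic evaluation of the symmetrized Pearson formula, written
# independently of the package implementation (explicit sums)
oracle_sym_pearson <- function(a, b) {
  vals <- c(a, b)
  m <- sum(vals) / length(vals)
  v <- sum((vals - m)^2) / length(vals)
  s <- 0
  for (i in seq_along(a)) {
    s <- s + (a[i] - m) * (b[i] - m) + (b[i] - m) * (a[i] - m)
  }
  (s / (2 * length(a))) / v
}
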