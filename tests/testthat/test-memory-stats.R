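# Pair correlation functions, windowed elongation rates, variance dynamics,
# exponential memory fits and bootstrap errors.

test_that("windowed elongation rate recovers exponential and linear growth laws", {
  # exact exponential: alpha constant at every admissible center
  tr <- exp_trace(n = 14, alpha = 0.02)
  cs <- segment_cycles(tr)
  wa <- windowed_alpha(cs, window_min = 6)
  expect_equal(nrow(wa), 12)  # centers exclude the two edge frames
  expect_equal(wa$alpha, rep(0.02, 12), tolerance = 1e-10)

  # linear growth L = L0 (1 + c t): alpha(t) = c / (1 + c t), decreasing;
  # compare against the finite-difference oracle on the same window
  cc <- 0.03
  tr2 <- exp_trace(n = 14)
  tr2$length <- 2 * (1 + cc * tr2$time_min)
  cs2 <- segment_cycles(tr2)
  wa2 <- windowed_alpha(cs2, window_min = 6)
  expect_true(all(diff(wa2$alpha) < 0))
  oracle <- (log(2 * (1 + cc * (wa2$time_min + 3))) -
             log(2 * (1 + cc * (wa2$time_min - 3)))) / 6
  expect_equal(wa2$alpha, oracle, tolerance = 1e-10)
  expect_equal(wa2$alpha, cc / (1 + cc * wa2$time_min), tolerance = 0.01)

  # windows never span a division: centers stop half a window short
  lin <- exp_lineage(n_cycles = 2, n = 8)
  cs3 <- segment_cycles(lin)
  wa3 <- windowed_alpha(cs3, window_min = 6)
  div_t <- cs3$cycles$division_time[1]
  expect_false(any(wa3$time_min == div_t))  # edge frames have no estimate

  expect_error(windowed_alpha(cs3, window_min = 2), "fewer than 2 frames")
})

test_that("the symmetrized PCF matches direct arithmetic evaluation exactly", {
  e1 <- hand_ensemble(cbind(c(1, 2, 3)), cbind(c(1, 2, 3)))
  expect_equal(pcf(e1, "T", 1), 1)
  e2 <- hand_ensemble(cbind(c(1, 2)), cbind(c(2, 1)))
  expect_error(pcf(e2, "T", 1), "fewer than 3")
  expect_equal(sistermem:::symmetrized_pearson(c(1, 2), c(2, 1)), -1)

  # oracle equivalence at 1e-12 on hand-built ensembles, plus the duplicated
  # Pearson identity cor(c(a,b), c(b,a))
  set.seed(41)
  for (k in 1:10) {
    n <- sample(3:10, 1)
    a <- rnorm(n); b <- a * runif(1, -1, 1) + rnorm(n, 0, 0.5)
    e <- hand_ensemble(cbind(a), cbind(b))
    v <- pcf(e, "T", 1)
    expect_equal(v, oracle_sym_pearson(a, b), tolerance = 1e-12)
    expect_equal(v, cor(c(a, b), c(b, a)), tolerance = 1e-12)
    # bounded and symmetric under member swap
    expect_true(v >= -1 && v <= 1)
    expect_equal(pcf(hand_ensemble(cbind(b), cbind(a)), "T", 1), v,
                 tolerance = 1e-14)
  }

  # conventional origin
  expect_equal(pcf(e1, "T", 0), 1)

  # degenerate: zero variance across pairs
  e0 <- hand_ensemble(cbind(c(2, 2, 2)), cbind(c(2, 2, 2)))
  expect_error(pcf(e0, "T", 1), "degenerate")
})

test_that("PCF series carries the convention at g = 0 and fits the decay", {
  set.seed(42)
  n <- 150
  rho_g <- function(g) 0.8 * 0.85^g
  g_max <- 8
  va <- vb <- matrix(0, n, g_max)
  for (g in 1:g_max) {
    shared <- rnorm(n)
    r <- rho_g(g)
    va[, g] <- sqrt(r) * shared + sqrt(1 - r) * rnorm(n)
    vb[, g] <- sqrt(r) * shared + sqrt(1 - r) * rnorm(n)
  }
  e <- hand_ensemble(va, vb)
  s <- pcf_by_generation(e, "T", g_max = g_max, n_boot = 100, seed = 1)
  expect_equal(s$values[1], 1)
  expect_equal(s$se[1], 0)
  expect_true(all(s$values >= -1 & s$values <= 1, na.rm = TRUE))
  # measured points near the constructed correlation (3 bootstrap SEs)
  for (g in c(1, 4, 8)) {
    expect_lt(abs(s$values[g + 1] - rho_g(g)), 3 * s$se[g + 1] + 0.05)
  }
  expect_false(is.null(s$fit))
})

test_that("lineage ACF: unity at lag zero, white noise flat, AR(1) closed form", {
  set.seed(43)
  n_lin <- 60; len <- 30
  # white noise property
  cy <- do.call(rbind, lapply(seq_len(n_lin), function(i) {
    data.frame(cell_id = sprintf("L%02d:g%d", i, 1:len),
               trap_id = sprintf("trap%02d", i), parent_id = "x",
               birth_time = 0, division_time = 30, T = rnorm(len),
               L_birth = 1, L_div = 2, alpha_cycle = 0.02, f_mean = 1,
               n_frames = 10L, lineage_id = sprintf("L%02d", i), gen = 1:len)
  }))
  cs <- structure(list(cycles = cy, frames = data.frame()), class = "cycle_set")
  a <- acf_lineage(cs, "T", lags = 0:3)
  expect_equal(a$values[1], 1)
  expect_lt(abs(a$values[2]), 3 / sqrt(n_lin * (len - 1)))

  # AR(1) with retention phi: ACF(g) = phi^g
  phi <- 0.8
  cy$T <- as.vector(vapply(seq_len(n_lin), function(i) {
    x <- numeric(len); x[1] <- rnorm(1)
    for (k in 2:len) x[k] <- phi * x[k - 1] + sqrt(1 - phi^2) * rnorm(1)
    x
  }, numeric(len)))
  cs2 <- structure(list(cycles = cy, frames = data.frame()), class = "cycle_set")
  a2 <- acf_lineage(cs2, "T", lags = 0:4)
  for (g in 1:4) {
    expect_equal(a2$values[g + 1], phi^g, tolerance = 0.08)
  }

  # degenerate input errors
  cy$T <- 1
  cs3 <- structure(list(cycles = cy, frames = data.frame()), class = "cycle_set")
  expect_error(acf_lineage(cs3, "T", lags = 0:2), "degenerate")
})

test_that("exponential fits recover half-lives, flag non-decay, and need 4 points", {
  g <- 0:10
  f <- fit_exponential(g, exp(-log(2) / 4.5 * g))
  expect_equal(f$half_life, 4.5, tolerance = 1e-6)
  expect_equal(f$A, 1, tolerance = 1e-6)

  f2 <- fit_exponential(0:3 * 1.0, rep(1, 4))
  expect_identical(f2$half_life, Inf)

  expect_error(fit_exponential(0:2, c(1, 0.5, 0.2)), "4 grid points")

  # noisy recovery: 5% additive noise, 11 points, 200 replicates
  set.seed(44)
  hl <- replicate(200, {
    y <- exp(-log(2) / 4 * g) + rnorm(11, 0, 0.05)
    fit_exponential(g, y)$half_life
  })
  expect_lt(abs(median(hl) - 4) / 4, 0.10)
})

test_that("difference-variance dynamics match the independent-OU closed form", {
  # identical members: all deltas zero, flat series, saturation at the origin
  d0 <- structure(list(property = "fluor", dt = 3,
                       deltas = data.frame(pair_id = rep(sprintf("P%d", 1:5), each = 10),
                                           t = rep(seq(0, 27, by = 3), 5),
                                           delta = 1)),
                  class = "delta_series")
  v0 <- variance_series(d0)
  expect_true(all(v0$var == 0))
  expect_equal(v0$saturation_time_min, 0)

  # independent OU members started equal: var = 2 sigma^2 (1 - e^(-2t/tau)),
  # 90%-of-plateau crossing near 1.151 tau
  set.seed(45)
  n <- 5000; tau <- 30; sig <- 1; dt <- 3
  tgrid <- seq(0, 150, by = dt)
  xa <- xb <- rep(0, n)
  del <- matrix(0, n, length(tgrid))
  for (k in 2:length(tgrid)) {
    xa <- ou_step(xa, dt, tau, sig)
    xb <- ou_step(xb, dt, tau, sig)
    del[, k] <- xa - xb
  }
  dd <- structure(list(property = "fluor", dt = dt,
                       deltas = data.frame(pair_id = rep(sprintf("P%04d", 1:n),
                                                         each = length(tgrid)),
                                           t = rep(tgrid, n),
                                           delta = as.vector(t(del)))),
                  class = "delta_series")
  vv <- variance_series(dd, smooth_frames = 1)
  theory <- 2 * sig^2 * (1 - exp(-2 * tgrid / tau))
  expect_equal(vv$var, theory, tolerance = 0.12)
  # band-entry estimator brackets the 90%-of-plateau crossing (1.151 tau);
  # it is biased late by the persistence requirement and grid resolution
  crossing <- -tau / 2 * log(0.1)
  expect_gte(vv$saturation_time_min, crossing - 2 * dt)
  expect_lte(vv$saturation_time_min, crossing + 5 * dt)
  # the pooled saturating-exponential fit pins the crossing tightly
  ft <- fit_saturation(vv)
  expect_equal(ft$t90, 1.151 * tau, tolerance = 0.1)
})

test_that("bootstrap errors are seeded, zero for degenerate statistics, ~sd/sqrt(n) for means", {
  set.seed(46)
  x <- rnorm(100)
  e <- hand_ensemble(cbind(x), cbind(x))
  se0 <- bootstrap_se(function(ens) 7, e, n_boot = 50, seed = 1)
  expect_identical(se0, 0)
  stat <- function(ens) mean(pair_gen_property_pub(ens))
  pair_gen_property_pub <- function(ens) sistermem:::pair_gen_property(ens, "T", 1)[, 1]
  s1 <- bootstrap_se(stat, e, n_boot = 400, seed = 2)
  s2 <- bootstrap_se(stat, e, n_boot = 400, seed = 2)
  expect_identical(s1, s2)
  expect_equal(s1, sd(x) / sqrt(100), tolerance = 0.1)
})

test_that("signed pair differences vanish for identical members and average to zero", {
  tab <- simulate_experiment(sim_config(n_traps = 30, n_generations = 10, seed = 8))
  cs <- segment_cycles(tab)
  sc <- build_sc_pairs(cs)
  ds <- delta_series(sc, "alpha")
  # grand mean of delta-alpha within 3 SEs of zero
  m <- mean(ds$deltas$delta)
  se <- sd(ds$deltas$delta) / sqrt(length(unique(ds$deltas$pair_id)))
  expect_lt(abs(m), 3 * se)

  # identical members: delta identically zero (trap-level variation only)
  tab2 <- simulate_experiment(noise_free_config(sigma_env_static = 0.1,
                                                n_traps = 6))
  cs2 <- segment_cycles(tab2)
  sc2 <- build_sc_pairs(cs2)
  ds2 <- delta_series(sc2, "alpha")
  expect_true(all(abs(ds2$deltas$delta) < 1e-12))
})

test_that("per-generation difference variance is flat without inherited factors", {
  # no heritable factors, no compensation: sisters decorrelate immediately,
  # so var(T_a - T_b) is flat in g (members independent given the trap)
  tab <- simulate_experiment(sim_config(sigma_hT = 0, sigma_hL = 0, kappa = 0,
                                        n_traps = 80, n_generations = 12,
                                        seed = 10))
  cs <- segment_cycles(tab)
  sc <- build_sc_pairs(cs)
  vg <- variance_by_generation(sc, "T", g_max = 8)
  sl <- coef(lm(vg$var ~ vg$grid))[2]
  se <- summary(lm(vg$var ~ vg$grid))$coefficients[2, 2]
  expect_lt(abs(sl), 3 * se)
})

test_that("growth-rate difference summary separates sisters from random pairs", {
  e_id <- hand_ensemble(matrix(rnorm(30), 5), matrix(0, 5, 6))
  e_id$cs$cycles$alpha_cycle <- e_id$cs$cycles$T
  # identical members: all sister samples zero
  a <- matrix(rnorm(30), 5)
  e_same <- hand_ensemble(a, a)
  s <- pair_rate_difference_summary(e_same, e_id, min_cycles = 5)
  expect_true(all(s$samples_sc == 0))
  expect_equal(s$ratio, 0)
  expect_error(pair_rate_difference_summary(e_same, e_id, min_cycles = 50),
               "no pairs")
})
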