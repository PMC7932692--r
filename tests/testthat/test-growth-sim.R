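# The generative kernels: OU noise, AR(1) inheritance, division partitioning,
# adder size control and the full sisters-machine simulator.

test_that("ou_step is exact: identity at dt = 0, stationary limit, preserved variance", {
  expect_identical(ou_step(1.7, dt = 0, tau = 5, sigma = 1), 1.7)
  expect_error(ou_step(0, dt = 1, tau = 0, sigma = 1), "tau")

  # dt >> tau: the new state is a fresh N(0, sigma^2) draw, independent of x
  set.seed(11)
  x0 <- seq(-5, 5, length.out = 2000)
  x1 <- ou_step(x0, dt = 1e9 * 5, tau = 5, sigma = 2)
  expect_lt(abs(cor(x0, x1)), 3 / sqrt(2000))
  expect_equal(sd(x1), 2, tolerance = 0.1)

  # iterated chain at dt = tau keeps the stationary variance (3 MC SEs,
  # accounting for the chain's autocorrelation a = exp(-1))
  set.seed(12)
  n <- 1e5
  x <- numeric(n)
  for (i in 2:n) x[i] <- ou_step(x[i - 1], dt = 5, tau = 5, sigma = 1)
  a2 <- exp(-2)
  se <- sqrt(2 * (1 + 2 * a2 / (1 - a2)) / n)
  expect_lt(abs(mean(x^2) - 1), 3 * se)

  # Kolmogorov-Smirnov against N(0, sigma^2) after many steps
  set.seed(13)
  y <- rnorm(1e4, 0, 3)  # start in the stationary law
  for (k in 1:5) y <- ou_step(y, dt = 2, tau = 5, sigma = 3)
  expect_gt(suppressWarnings(ks.test(y, "pnorm", 0, 3)$p.value), 0.01)
})

test_that("inherited factors follow the AR(1) law and the phi^(2g) sister correlation", {
  expect_error(update_inherited_factor(0, phi = 1.2, sigma_h = 1), "phi")
  set.seed(21)
  expect_identical(update_inherited_factor(c(1, -2), phi = 1, sigma_h = 3),
                   c(1, -2))
  set.seed(22)
  h <- update_inherited_factor(rep(100, 5000), phi = 0, sigma_h = 2)
  expect_equal(mean(h), 0, tolerance = 3 * 2 / sqrt(5000))
  expect_equal(sd(h), 2, tolerance = 0.1)

  # sisters drawn independently from a common mother, then iterated g - 1
  # more generations each: corr at generation g is phi^(2g)
  phi <- 2^(-1 / 9)
  n <- 2e4
  set.seed(23)
  for (g in c(1, 2, 4, 8)) {
    mom <- rnorm(n)  # stationary, sigma_h = 1
    a <- update_inherited_factor(mom, phi, 1)
    b <- update_inherited_factor(mom, phi, 1)
    if (g > 1) for (k in 2:g) {
      a <- update_inherited_factor(a, phi, 1)
      b <- update_inherited_factor(b, phi, 1)
    }
    rho <- phi^(2 * g)
    se <- (1 - rho^2) / sqrt(n)
    expect_lt(abs(cor(a, b) - rho), 3 * se)
  }
  # algebraic anchor: at g = 9 with phi = 2^(-1/9) the correlation is 1/4
  expect_equal((2^(-1 / 9))^18, 0.25)
})

test_that("division partitioning conserves length, concentration and flips compensation", {
  cfg <- sim_config(kappa = 2, seed = 1)
  st <- list(length = 4, h_T = 0.1, h_L = -0.05, f = 123, birth_time = 10,
             trap_id = "t", cell_id = "c", c0 = 0)
  set.seed(31)
  d <- partition_at_division(st, r = 0.5, cfg, time = 40)
  expect_equal(d$first$length, 2)
  expect_equal(d$second$length, 2)
  expect_equal(d$first$c0, 0)
  expect_equal(d$first$f, 123)
  expect_equal(d$second$f, 123)

  d <- partition_at_division(st, r = 0.3, cfg, time = 40)
  expect_equal(d$first$length, 1.2)
  expect_equal(d$second$length, 2.8)
  expect_equal(d$first$length + d$second$length, st$length)
  # amplitudes +/- alpha_bar * kappa * 0.4, small sister faster
  expect_equal(d$first$c0, cfg$alpha_bar * 2 * 0.4)
  expect_equal(d$second$c0, -cfg$alpha_bar * 2 * 0.4)
  expect_equal(d$first$birth_time, 40)
  expect_equal(d$first$parent_id, "c")

  expect_error(partition_at_division(st, r = 1, cfg), "r")
  expect_error(partition_at_division(st, r = -0.1, cfg), "r")
})

test_that("noise-free growth is exactly exponential and compensation decays as exp(-t/tau_c)", {
  cfg <- noise_free_config()
  trap <- list(eps_static = 0, eps_dyn = 0)
  st <- list(length = 1.5, h_T = 0, h_L = 0, xi = 0, c0 = 0, f = 100,
             birth_time = 0, trap_id = "t", cell_id = "c")
  for (k in 1:20) st <- advance_cell(st, trap, cfg, dt = 3, time = 3 * (k - 1))
  expect_equal(st$length, 1.5 * exp(cfg$alpha_bar * 60), tolerance = 1e-12)

  # compensation-only sisters (r != 0.5): rate difference 2 a kappa (1-2r)
  # at separation, decaying exponentially with tau_c
  cfg2 <- noise_free_config(kappa = 1.5)
  r <- 0.3
  c0 <- cfg2$alpha_bar * cfg2$kappa * (1 - 2 * r)
  for (t in c(0, 6, 15, 30)) {
    da <- instantaneous_alpha(cfg2, 0, 0, 0, 0, c0, t) -
      instantaneous_alpha(cfg2, 0, 0, 0, 0, -c0, t)
    expect_equal(da, 2 * cfg2$alpha_bar * cfg2$kappa * (1 - 2 * r) *
                   exp(-t / cfg2$tau_c), tolerance = 1e-12)
  }
})

test_that("the adder reaches its fixed point: birth length delta_bar, cycle time ln2/alpha", {
  # brute-force scalar simulation at fine time resolution, no noise
  cfg <- noise_free_config()
  trap <- list(eps_static = 0, eps_dyn = 0)
  st <- list(length = 3.17, h_T = 0, h_L = 0, xi = 0, c0 = 0, f = 100,
             birth_time = 0, trap_id = "t", cell_id = "c",
             birth_length = 3.17, adder_target = cfg$delta_bar)
  dt <- 0.05
  t <- 0
  births <- c()
  times <- c()
  while (length(births) < 12) {
    st <- advance_cell(st, trap, cfg, dt = dt, time = t)
    t <- t + dt
    if (divide_when_adder_met(st)) {
      births <- c(births, st$length / 2)
      times <- c(times, t)
      st$length <- st$length / 2
      st$birth_length <- st$length
      st$adder_target <- cfg$delta_bar
    }
  }
  expect_equal(births[12], cfg$delta_bar, tolerance = 0.01)
  expect_equal(diff(times)[11], log(2) / cfg$alpha_bar, tolerance = 0.01)

  # pure adder property: doubling delta_bar leaves the cycle time at ln2/alpha
  cfg2 <- noise_free_config(delta_bar = 4)
  st <- list(length = 4.7, h_T = 0, h_L = 0, xi = 0, c0 = 0, f = 100,
             birth_time = 0, trap_id = "t", cell_id = "c",
             birth_length = 4.7, adder_target = cfg2$delta_bar)
  t <- 0; times <- c()
  while (length(times) < 12) {
    st <- advance_cell(st, trap, cfg2, dt = dt, time = t)
    t <- t + dt
    if (divide_when_adder_met(st)) {
      times <- c(times, t)
      st$length <- st$length / 2
      st$birth_length <- st$length
      st$adder_target <- cfg2$delta_bar
    }
  }
  expect_equal(diff(times)[11], log(2) / cfg2$alpha_bar, tolerance = 0.01)

  # heritable adder factor scales the increment
  cfg3 <- sim_config(seed = 1)
  expect_equal(sistermem:::adder_target(cfg3, h_L = 0.1, z = 0),
               1.1 * cfg3$delta_bar)
})

test_that("simulate_experiment is deterministic and validates its inputs", {
  cfg <- tiny_config(seed = 42)
  t1 <- simulate_experiment(cfg)
  t2 <- simulate_experiment(cfg)
  expect_identical(t1, t2)
  t3 <- simulate_experiment(tiny_config(seed = 43))
  expect_false(identical(t1, t3))
  expect_error(sim_config(n_generations = 1), "n_generations")
  expect_error(sim_config(n_traps = 0), "n_traps")
  expect_error(sim_config(phony = 1), "unknown")
})

test_that("noise-free simulation: identical cycle times, sisters indistinguishable", {
  tab <- simulate_experiment(noise_free_config(n_generations = 12))
  cs <- segment_cycles(tab)
  # on the frame grid a noise-free adder settles into a limit cycle whose
  # period is not a whole number of frames, so recorded cycle times alternate
  # between two adjacent frame counts; beyond that quantization the ensemble
  # is exactly homogeneous
  interior <- cs$cycles$T[cs$cycles$gen >= 6]
  expect_gt(length(interior), 30)
  expect_lte(diff(range(interior)), 3 + 1e-9)
  expect_lte(length(unique(interior)), 2)
  sc <- build_sc_pairs(cs)
  expect_error(pcf(sc, "T", g = 2), "degenerate|fewer")
})

test_that("with only trap-level variation, sister PCF is exactly 1 at every generation", {
  # members identical within a pair, traps differ: perfect correlation
  tab <- simulate_experiment(noise_free_config(sigma_env_static = 0.1,
                                               n_traps = 8))
  cs <- segment_cycles(tab)
  sc <- build_sc_pairs(cs)
  for (g in 1:4) {
    expect_equal(pcf(sc, "T", g = g), 1, tolerance = 1e-9)
  }
})

test_that("simulated ensembles reproduce the mean generation time and imaging cadence", {
  tab <- simulate_experiment(sim_config(n_traps = 40, n_generations = 14,
                                        seed = 7))
  cs <- segment_cycles(tab)
  expect_equal(mean(cs$cycles$T), 34, tolerance = 0.1)
  expect_equal(mean(cs$cycles$n_frames - 1), 11, tolerance = 0.15)
})
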