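#' Exact Ornstein-Uhlenbeck update
#'
#' Advances a zero-mean OU state by `dt` using the exact discretization
#' `x' = x e^(-dt/tau) + sigma sqrt(1 - e^(-2 dt/tau)) z`, `z ~ N(0, 1)`.
#' The stationary distribution `N(0, sigma^2)` is preserved for any step size.
#'
#' @param x Numeric vector of OU states.
#' @param dt Time step (same units as `tau`); `dt >= 0`.
#' @param tau Correlation time; must be positive.
#' @param sigma Stationary standard deviation; `sigma >= 0`.
#' @return Updated state vector, same length as `x`.
#' @examples
#' set.seed(1)
#' ou_step(0, dt = 5, tau = 5, sigma = 1)
#' @export
ou_step <- function(x, dt, tau, sigma) {
  if (!is.numeric(tau) || tau <= 0) {
    stop("ou_step: 'tau' must be positive", call. = FALSE)
  }
  if (dt < 0) stop("ou_step: 'dt' must be non-negative", call. = FALSE)
  if (sigma < 0) stop("ou_step: 'sigma' must be non-negative", call. = FALSE)
  if (dt == 0) return(x)
  a <- exp(-dt / tau)
  x * a + sigma * sqrt(1 - a^2) * stats::rnorm(length(x))
}

#' Inherit an AR(1) factor across a division
#'
#' Draws a daughter's heritable factor from the mother's:
#' `h' = phi h + sqrt(1 - phi^2) sigma_h z`. Each daughter draws
#' independently, so the sister-sister correlation of the factor at
#' generation `g` after the common division is `phi^(2 g)` and the stationary
#' variance is `sigma_h^2`.
#'
#' @param h_mother Mother's factor value(s).
#' @param phi Per-generation retention, in `[0, 1]`.
#' @param sigma_h Stationary standard deviation.
#' @return Daughter factor value(s).
#' @export
update_inherited_factor <- function(h_mother, phi, sigma_h) {
  if (!is.numeric(phi) || any(phi < 0) || any(phi > 1)) {
    stop("update_inherited_factor: 'phi' must lie in [0, 1]", call. = FALSE)
  }
  if (any(sigma_h < 0)) {
    stop("update_inherited_factor: 'sigma_h' must be non-negative", call. = FALSE)
  }
  phi * h_mother + sqrt(1 - phi^2) * sigma_h * stats::rnorm(length(h_mother))
}

#' Partition a cell at division
#'
#' Splits a cell state into two daughters receiving length fractions `r` and
#' `1 - r` (lengths sum to the mother's exactly). Both daughters inherit the
#' mother's protein concentration (symmetric partitioning of soluble
#' protein). Compensation amplitudes are opposite:
#' `alpha_bar * kappa * (1 - 2 r)` for the `r` daughter, so the smaller sister
#' transiently grows faster. Heritable factors are redrawn independently per
#' daughter via [update_inherited_factor()].
#'
#' @param state A cell state: a list with at least `length`, `h_T`, `h_L`,
#'   `f`, `birth_time`, `trap_id`, `cell_id`.
#' @param r Division fraction in `(0, 1)` given to the first daughter.
#' @param cfg A [sim_config()].
#' @param time Division time (minutes); becomes the daughters' `birth_time`.
#' @return List of two daughter states (`first` gets fraction `r`).
#' @export
partition_at_division <- function(state, r, cfg, time = state$birth_time) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0 || r >= 1) {
    stop("partition_at_division: 'r' must lie strictly in (0, 1)", call. = FALSE)
  }
  mk <- function(frac) {
    d <- state
    d$length <- frac * state$length
    d$birth_length <- d$length
    d$h_T <- update_inherited_factor(state$h_T, cfg$phi_T, cfg$sigma_hT)
    d$h_L <- update_inherited_factor(state$h_L, cfg$phi_L, cfg$sigma_hL)
    d$c0 <- cfg$alpha_bar * cfg$kappa * (1 - 2 * frac)
    d$f <- state$f
    d$birth_time <- time
    d$parent_id <- state$cell_id
    d$adder_target <- adder_target(cfg, d$h_L, stats::rnorm(1))
    d
  }
  list(first = mk(r), second = mk(1 - r))
}

# Adder increment drawn at birth; clamped away from zero so pathological
# noise draws cannot produce a non-growing cycle.
adder_target <- function(cfg, h_L, z) {
  pmax(cfg$delta_bar * (1 + h_L) * (1 + cfg$sigma_delta_rel * z),
       0.1 * cfg$delta_bar)
}

#' Instantaneous elongation rate of the generative model
#'
#' `alpha(t) = alpha_bar (1 + h_T + eps_static + eps_dyn + xi) +
#'  alpha_bar kappa (1 - 2 r) e^(-t_since_birth / tau_c)`; the last term is
#' the post-division compensation, inversely scaling with the inherited size
#' fraction.
#'
#' @param cfg A [sim_config()].
#' @param h_T,xi,eps_static,eps_dyn Latent state components.
#' @param c0 Compensation amplitude set at birth (absolute rate units).
#' @param t_since_birth Minutes since birth.
#' @return Instantaneous rate (1/min).
#' @export
instantaneous_alpha <- function(cfg, h_T, xi, eps_static, eps_dyn, c0,
                                t_since_birth) {
  cfg$alpha_bar * (1 + h_T + eps_static + eps_dyn + xi) +
    c0 * exp(-t_since_birth / cfg$tau_c)
}

#' Advance one cell state over a frame interval
#'
#' Grows the cell exponentially at the current instantaneous rate (held
#' constant over the sub-step), then advances the intrinsic growth noise and
#' protein concentration by their exact OU updates. The trap state is advanced
#' separately (it is shared between the trap's two cells).
#'
#' @param state Cell state list (see [partition_at_division()]).
#' @param trap Trap state: list with `eps_static`, `eps_dyn`.
#' @param cfg A [sim_config()].
#' @param dt Step in minutes (normally `cfg$dt_min`).
#' @param time Current time (minutes).
#' @return Updated cell state.
#' @export
advance_cell <- function(state, trap, cfg, dt, time) {
  a <- instantaneous_alpha(cfg, state$h_T, state$xi, trap$eps_static,
                           trap$eps_dyn, state$c0, time - state$birth_time)
  state$length <- state$length * exp(a * dt)
  state$xi <- ou_step(state$xi, dt, cfg$tau_xi, cfg$sigma_xi)
  f_target <- cfg$f_bar * (1 + cfg$beta_f * trap$eps_static)
  state$f <- f_target + ou_step(state$f - f_target, dt, cfg$tau_f,
                                cfg$sigma_f_intr)
  state
}

#' Adder division test
#'
#' A cell divides once it has added its adder increment since birth:
#' `length - birth_length >= delta_bar (1 + h_L)(1 + eta)` with the increment
#' drawn once at birth.
#'
#' @param state Cell state with `length`, `birth_length`, `adder_target`.
#' @return Logical: division triggered.
#' @export
divide_when_adder_met <- function(state) {
  state$length - state$birth_length >= state$adder_target
}

#' Simulate a sisters-machine experiment
#'
#' For each v-trap, a founder mother is burned in to stationarity
#' (`burnin_generations` full cycles), then its next division seeds the two
#' tips of the trap with the two sister daughters at movie time 0. Each tip
#' thereafter tracks one (seeded-random) daughter per division, as the device
#' tip does physically. Frames are recorded every `dt_min` minutes with
#' multiplicative log-normal measurement noise and ground-truth division
#' flags; the movie spans `n_generations` mean generation times.
#'
#' @param cfg A [sim_config()].
#' @return A lineage table: `data.frame` with columns `trap_id`, `cell_id`,
#'   `parent_id`, `frame`, `time_min`, `length`, `fluor`, `division`, one row
#'   per cell per frame, sorted by trap, cell and frame. Each tracked cell
#'   cycle carries its own `cell_id`; `division == 1` marks the last frame of
#'   a cycle. Deterministic given `cfg$seed`.
#' @examples
#' tab <- simulate_experiment(sim_config(n_traps = 2, n_generations = 4, seed = 1))
#' head(tab)
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(cfg$seed)

  nt <- cfg$n_traps
  dt <- cfg$dt_min
  ab <- cfg$alpha_bar
  tbar <- log(2) / ab

  trap_ids <- sprintf("trap%03d", seq_len(nt))
  eps_s <- stats::rnorm(nt, 0, cfg$sigma_env_static)
  eps_d <- stats::rnorm(nt, 0, cfg$sigma_env_dyn)

  # --- burn-in: one mother per trap ------------------------------------------
  hT <- stats::rnorm(nt, 0, cfg$sigma_hT)
  hL <- stats::rnorm(nt, 0, cfg$sigma_hL)
  xi <- stats::rnorm(nt, 0, cfg$sigma_xi)
  Lb <- cfg$delta_bar * (1 + hL)
  L <- Lb
  Dtgt <- adder_target(cfg, hL, stats::rnorm(nt))
  f_target <- cfg$f_bar * (1 + cfg$beta_f * eps_s)
  f <- f_target + stats::rnorm(nt, 0, cfg$sigma_f_intr)
  tb <- rep(0, nt)       # time since birth
  gens <- rep(0L, nt)    # completed cycles during burn-in
  founded <- rep(FALSE, nt)

  # founding daughters' state, filled as traps found
  n_cells <- 2L * nt
  c_trap <- rep(seq_len(nt), each = 2L)
  c_side <- rep(c("a", "b"), nt)  # tip side within the v-trap
  cL <- cLb <- cD <- chT <- chL <- cxi <- cc0 <- cf <- ctb <- numeric(n_cells)
  c_count <- rep(1L, n_cells)  # per-tip cycle counter for ids
  c_id <- character(n_cells)
  c_parent <- character(n_cells)

  max_burn_frames <- ceiling((cfg$burnin_generations + 12) * 2 * tbar / dt)
  for (k in seq_len(max_burn_frames)) {
    if (all(founded)) break
    act <- which(!founded)
    a <- ab * (1 + hT[act] + eps_s[act] + eps_d[act] + xi[act])
    L[act] <- L[act] * exp(a * dt)
    xi[act] <- ou_step(xi[act], dt, cfg$tau_xi, cfg$sigma_xi)
    f[act] <- f_target[act] +
      ou_step(f[act] - f_target[act], dt, cfg$tau_f, cfg$sigma_f_intr)
    eps_d <- ou_step(eps_d, dt, cfg$tau_env, cfg$sigma_env_dyn)
    tb[act] <- tb[act] + dt

    div <- act[L[act] - Lb[act] >= Dtgt[act]]
    if (length(div)) {
      gens[div] <- gens[div] + 1L
      r <- division_fraction(length(div), cfg$sigma_r)
      ripe <- gens[div] > cfg$burnin_generations
      # traps reaching the founding division: split into two tracked sisters
      for (jj in which(ripe)) {
        i <- div[jj]
        mother_id <- sprintf("%s:m0000", trap_ids[i])
        for (side in 1:2) {
          j <- 2L * (i - 1L) + side
          frac <- if (side == 1L) r[jj] else 1 - r[jj]
          cL[j] <- frac * L[i]
          cLb[j] <- cL[j]
          chT[j] <- update_inherited_factor(hT[i], cfg$phi_T, cfg$sigma_hT)
          chL[j] <- update_inherited_factor(hL[i], cfg$phi_L, cfg$sigma_hL)
          cD[j] <- adder_target(cfg, chL[j], stats::rnorm(1))
          cxi[j] <- xi[i]
          cc0[j] <- ab * cfg$kappa * (1 - 2 * frac)
          cf[j] <- f[i]
          ctb[j] <- 0
          c_id[j] <- sprintf("%s:%s%04d", trap_ids[i], c_side[j], 1L)
          c_parent[j] <- mother_id
        }
        founded[i] <- TRUE
      }
      # others keep one daughter and continue burn-in
      keep <- which(!ripe)
      if (length(keep)) {
        i <- div[keep]
        frac <- r[keep]
        L[i] <- frac * L[i]
        Lb[i] <- L[i]
        hT[i] <- update_inherited_factor(hT[i], cfg$phi_T, cfg$sigma_hT)
        hL[i] <- update_inherited_factor(hL[i], cfg$phi_L, cfg$sigma_hL)
        Dtgt[i] <- adder_target(cfg, hL[i], stats::rnorm(length(i)))
        tb[i] <- 0
      }
    }
  }
  if (!all(founded)) {
    stop("simulate_experiment: burn-in failed to converge; check growth parameters",
         call. = FALSE)
  }

  # --- movie: two tracked tips per trap, common frame clock ------------------
  n_frames <- ceiling(cfg$n_generations * tbar / dt) + 1L
  cell_trap_id <- trap_ids[c_trap]
  f_target2_pre <- f_target[c_trap]

  # advance the founding daughters one frame before recording starts, so that
  # their first recorded frame sits one cadence step after birth, exactly as
  # for every later daughter (frame 0 is dt minutes after the founding
  # division)
  a0 <- ab * (1 + chT + eps_s[c_trap] + eps_d[c_trap] + cxi) +
    cc0 * exp(-ctb / cfg$tau_c)
  cL <- cL * exp(a0 * dt)
  cxi <- ou_step(cxi, dt, cfg$tau_xi, cfg$sigma_xi)
  cf <- f_target2_pre + ou_step(cf - f_target2_pre, dt, cfg$tau_f,
                                cfg$sigma_f_intr)
  eps_d <- ou_step(eps_d, dt, cfg$tau_env, cfg$sigma_env_dyn)
  ctb <- ctb + dt

  rows_trap <- vector("list", n_frames)
  rows_cell <- vector("list", n_frames)
  rows_parent <- vector("list", n_frames)
  rows_frame <- vector("list", n_frames)
  rows_time <- vector("list", n_frames)
  rows_len <- vector("list", n_frames)
  rows_fluor <- vector("list", n_frames)
  rows_div <- vector("list", n_frames)

  f_target2 <- f_target[c_trap]

  for (k in seq_len(n_frames)) {
    t_now <- (k - 1L) * dt
    dividing <- (cL - cLb) >= cD

    # record the current frame (division flag marks the last frame of a cycle)
    obs_L <- cL * exp(stats::rnorm(n_cells, 0, cfg$sigma_meas_L))
    obs_f <- cf * exp(stats::rnorm(n_cells, 0, cfg$sigma_meas_f))
    rows_trap[[k]] <- cell_trap_id
    rows_cell[[k]] <- c_id
    rows_parent[[k]] <- c_parent
    rows_frame[[k]] <- rep.int(k - 1L, n_cells)
    rows_time[[k]] <- rep.int(t_now, n_cells)
    rows_len[[k]] <- obs_L
    rows_fluor[[k]] <- obs_f
    rows_div[[k]] <- as.integer(dividing)

    if (k == n_frames) break

    # replace dividing cells by one tracked daughter each
    div <- which(dividing)
    if (length(div)) {
      frac <- division_fraction(length(div), cfg$sigma_r)
      mother_id <- c_id[div]
      mother_L <- cL[div]
      cL[div] <- frac * mother_L
      cLb[div] <- cL[div]
      chT[div] <- update_inherited_factor(chT[div], cfg$phi_T, cfg$sigma_hT)
      chL[div] <- update_inherited_factor(chL[div], cfg$phi_L, cfg$sigma_hL)
      cD[div] <- adder_target(cfg, chL[div], stats::rnorm(length(div)))
      cc0[div] <- ab * cfg$kappa * (1 - 2 * frac)
      ctb[div] <- 0
      c_count[div] <- c_count[div] + 1L
      c_id[div] <- sprintf("%s:%s%04d", trap_ids[c_trap[div]], c_side[div],
                           c_count[div])
      c_parent[div] <- mother_id
    }

    # grow and advance noises over [t, t + dt]
    a <- ab * (1 + chT + eps_s[c_trap] + eps_d[c_trap] + cxi) +
      cc0 * exp(-ctb / cfg$tau_c)
    cL <- cL * exp(a * dt)
    cxi <- ou_step(cxi, dt, cfg$tau_xi, cfg$sigma_xi)
    cf <- f_target2 + ou_step(cf - f_target2, dt, cfg$tau_f, cfg$sigma_f_intr)
    eps_d <- ou_step(eps_d, dt, cfg$tau_env, cfg$sigma_env_dyn)
    ctb <- ctb + dt
  }

  out <- data.frame(
    trap_id = unlist(rows_trap),
    cell_id = unlist(rows_cell),
    parent_id = unlist(rows_parent),
    frame = unlist(rows_frame),
    time_min = unlist(rows_time),
    length = unlist(rows_len),
    fluor = unlist(rows_fluor),
    division = unlist(rows_div),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$trap_id, out$cell_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Division fraction r ~ N(0.5, sigma_r), truncated at 3 SD so r and 1 - r stay
# in (0, 1); the tracked daughter's side is random by the symmetry of r.
division_fraction <- function(n, sigma_r) {
  z <- pmax(pmin(stats::rnorm(n), 3), -3)
  0.5 + sigma_r * z
}
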