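#' Noise-driven hazard component A
#'
#' Probability intensity for a neuron to cross threshold because of membrane
#' noise, as a function of the scaled threshold distance
#' `T = (V_T - V) / (sqrt(2) sigma_m)`. Polynomial-exponential approximation
#' of the self-similar hazard of the refractory-density theory; strictly
#' positive and decreasing for `T >= 0`.
#'
#' @param T scaled threshold distance (dimensionless), any finite value.
#' @return dimensionless probability intensity (multiply by `1/tau_M` for a
#'   rate).
#' @export
hazard_A <- function(T) {
  exp(0.0061 - 1.12 * T - 0.257 * T^2 - 0.072 * T^3 - 0.0117 * T^4)
}

#' Drift-response factor F_T
#'
#' `F_T = sqrt(2/pi) exp(-T^2) / (1 + erf(T))`: the firing probability factor
#' in the regime of fast changes of the scaled threshold distance.
#'
#' @param T scaled threshold distance (dimensionless).
#' @return positive factor.
#' @export
hazard_FT <- function(T) {
  # 1 + erf(T) = 2 pnorm(T sqrt(2)); evaluated through the log CDF so the
  # far-suprathreshold tail (very negative T) cannot underflow
  logden <- log(2) + stats::pnorm(sqrt(2) * T, log.p = TRUE)
  sqrt(2 / pi) * exp(-T^2 - logden)
}

#' Total hazard rate H
#'
#' `H = (A + B) / tau_M` with the drift component
#' `B = 2 max(-dT/dt, 0) F_T tau_M`: only depolarizing drift (V rising, hence
#' T falling) adds to the noise hazard. Grid points still inside the absolute
#' refractory period (`t_star < refractory`) have `H = 0`.
#'
#' @param T scaled threshold distance (dimensionless), vector.
#' @param dT_dt time derivative of `T` (1/ms), vector.
#' @param tau_M membrane time constant `C_m / g_tot` (ms), scalar.
#' @param t_star refractory ages of the grid points (ms), or `NULL` to skip
#'   refractory masking.
#' @param refractory absolute refractory period (ms).
#' @return hazard rate (1/ms), `>= 0`, same length as `T`.
#' @export
hazard_rate <- function(T, dT_dt, tau_M, t_star = NULL, refractory = 0) {
  stopifnot(tau_M > 0)
  H <- hazard_A(T) / tau_M + 2 * pmax(-dT_dt, 0) * hazard_FT(T)
  if (!is.null(t_star)) H[t_star < refractory] <- 0
  H
}

#' Refractory-density grid
#'
#' The CBRD state of one population: the density `rho(t_star)` of neurons
#' over refractory age and their mean membrane potential `V(t_star)`, on an
#' `N`-point uniform age grid of resolution `dt_star`. The density integrates
#' to one (`sum(rho) * dt_star = 1`). The initial condition places all mass
#' in the oldest age bin with `V = V_init` everywhere.
#'
#' @param N number of age-grid points (default 400).
#' @param dt_star age resolution (ms, default 0.5).
#' @param dt time step (ms, default 0.1); the scheme requires
#'   `dt / dt_star <= 1` (CFL condition).
#' @param V_init initial membrane potential (mV).
#' @return an object of class `density_grid` with fields `rho`, `V`,
#'   `t_star`, `dt_star`, `dt`, `N`.
#' @export
density_grid <- function(N = 400, dt_star = 0.5, dt = 0.1, V_init = -60) {
  stopifnot(N >= 3, dt_star > 0, dt > 0)
  if (dt / dt_star > 1 + 1e-12) {
    stop("CFL violation: dt / dt_star must be <= 1")
  }
  rho <- numeric(N)
  rho[N] <- 1 / dt_star
  structure(
    list(rho = rho, V = rep(V_init, N), t_star = (seq_len(N) - 1) * dt_star,
         dt_star = dt_star, dt = dt, N = N),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "density_grid: N = %d, dt_star = %g ms, dt = %g ms, mass = %.6f\n",
    x$N, x$dt_star, x$dt, sum(x$rho) * x$dt_star))
  invisible(x)
}

#' Flux limiter of the transport scheme
#'
#' Monotonized-central limiter compatible with the second-order upwind
#' correction: `sign(a) min(0.5 |a + b|, 2 |a|, 2 |b|)`, and 0 whenever
#' `a b <= 0` (local extremum).
#'
#' @param a forward difference `z[i+1] - z[i]`.
#' @param b backward difference `z[i] - z[i-1]`.
#' @return limited slope, vectorized over `a`, `b`.
#' @export
flux_limiter <- function(a, b) {
  out <- numeric(length(a))
  pos <- a * b > 0
  if (any(pos)) {
    m <- pmin(0.5 * abs(a + b), 2 * abs(a), 2 * abs(b))
    out[pos] <- (sign(a) * m)[pos]
  }
  out
}

#' One transport step of the refractory-density equations
#'
#' Advances `rho` and `V` along the refractory-age axis by the flux-limited
#' second-order upwind scheme, applying the hazard sink `-rho H` (in its
#' exactly integrated per-step form `rho expm1(-H dt) / dt`, stable for
#' arbitrarily large hazards) to the density and the membrane drift `dV/dt`
#' to the potential. Interior points
#' and the right (oldest-age, absorbing) boundary are updated; the left
#' boundary is completed by [boundary_update()], which re-injects the fired
#' mass at `t_star = 0`.
#'
#' @param grid a [density_grid()].
#' @param hazard hazard rate per grid point (1/ms).
#' @param drift membrane drift `dV/dt` per grid point (mV/ms).
#' @return the updated [density_grid()], carrying the left-boundary bookkeeping
#'   consumed by [boundary_update()].
#' @export
transport_step <- function(grid, hazard, drift) {
  stopifnot(inherits(grid, "density_grid"),
            length(hazard) == grid$N, length(drift) == grid$N)
  cfl <- grid$dt / grid$dt_star
  if (cfl > 1 + 1e-12) stop("CFL violation: dt / dt_star must be <= 1")
  N <- grid$N
  dt <- grid$dt
  step_one <- function(z, src, accumulate_right) {
    # limited slopes; boundary slopes are zero
    w <- numeric(N)
    idx <- 2:(N - 1)
    w[idx] <- flux_limiter(z[idx + 1] - z[idx], z[idx] - z[idx - 1])
    znew <- z
    znew[idx] <- z[idx] -
      cfl * (z[idx] - z[idx - 1] + 0.5 * (1 - cfl) * (w[idx] - w[idx - 1])) +
      dt * src[idx]
    # right boundary: the density's oldest-age bin absorbs the advective
    # inflow; the potential there only follows its drift
    znew[N] <- z[N] + dt * src[N]
    if (accumulate_right) {
      znew[N] <- znew[N] + cfl * (z[N - 1] + 0.5 * (1 - cfl) * w[N - 1])
    }
    znew
  }
  # the age-zero bin can never fire (a neuron there is mid-spike), which
  # also makes the re-injection bookkeeping exactly mass-conserving
  hazard[1] <- 0
  # exponential hazard sink: exact single-bin removal, stable for any H
  src_rho <- grid$rho * expm1(-hazard * dt) / dt
  out <- grid
  out$rho <- step_one(grid$rho, src_rho, accumulate_right = TRUE)
  out$V <- step_one(grid$V, drift, accumulate_right = FALSE)
  attr(out, "rho0_old") <- grid$rho[1]
  attr(out, "sink_sum") <- sum(src_rho)
  out
}

#' Boundary update and population firing rate
#'
#' Completes a transport step at the age boundaries: the left density bin
#' receives all probability mass removed by the hazard sink (fired neurons
#' re-enter at `t_star = 0`), the left potential is reset to `V_reset`, and
#' the population firing rate is read off as `nu = rho(t, 0)` (spikes/ms).
#' Together with the conservative interior scheme this keeps the total mass
#' `sum(rho) dt_star = 1` to machine precision.
#'
#' @param grid a [density_grid()] returned by [transport_step()].
#' @param V_reset reset potential (mV).
#' @return list with elements `grid` (updated [density_grid()]) and `nu`
#'   (firing rate, spikes/ms).
#' @export
boundary_update <- function(grid, V_reset = -90) {
  stopifnot(inherits(grid, "density_grid"))
  rho0_old <- attr(grid, "rho0_old")
  sink_sum <- attr(grid, "sink_sum")
  if (is.null(rho0_old) || is.null(sink_sum)) {
    stop("boundary_update expects the grid returned by transport_step()")
  }
  cfl <- grid$dt / grid$dt_star
  grid$rho[1] <- rho0_old - cfl * rho0_old - grid$dt * sink_sum
  grid$V[1] <- V_reset
  attr(grid, "rho0_old") <- NULL
  attr(grid, "sink_sum") <- NULL
  list(grid = grid, nu = grid$rho[1])
}

drives_matrix <- function(cfg, times, theta_hz = NULL, drives = NULL) {
  ext <- external_populations(cfg)
  if (length(ext) == 0) {
    return(matrix(0, nrow = length(times), ncol = 0))
  }
  mat <- matrix(0, nrow = length(times), ncol = length(ext),
                dimnames = list(NULL, ext))
  for (e in ext) {
    if (!is.null(drives) && !is.null(drives[[e]])) {
      tr <- drives[[e]]
      stopifnot(inherits(tr, "rate_trace"))
      mat[, e] <- stats::approx(tr$times, tr$rates, xout = times, rule = 2)$y
    } else {
      pr <- cfg$populations[[e]]$target
      if (is.null(pr)) {
        stop(sprintf("external population '%s' has no target profile and no drive was given", e))
      }
      if (!is.null(theta_hz)) {
        pr <- theta_profile_params(pr$FR_mean, pr$R, theta_hz, pr$phi)
      }
      mat[, e] <- rate_profile(pr, times, population = e)$rates
    }
  }
  mat / 1000 # spikes/s -> spikes/ms
}

cfg_arrays <- function(cfg) {
  sim <- simulated_populations(cfg)
  ext <- external_populations(cfg)
  pops <- cfg$populations[sim]
  getp <- function(f) vapply(pops, `[[`, 0, f)
  pre_code <- integer(cfg$M)
  post_code <- integer(cfg$M)
  for (j in seq_along(cfg$connections)) {
    cn <- cfg$connections[[j]]
    pre_code[j] <- if (cn$pre %in% sim) match(cn$pre, sim) else -match(cn$pre, ext)
    post_code[j] <- match(cn$post, sim)
  }
  getc <- function(f) {
    vapply(cfg$connections, function(cn) cn$params[[f]], 0)
  }
  list(
    sim = sim, ext = ext,
    Cm = getp("C_m"), gL = getp("g_L"), EL = getp("E_L"), VT = getp("V_T"),
    Vreset = getp("V_reset"), sigma = getp("sigma_m"),
    refr = getp("refractory"), Iext = getp("I_ext"),
    pre = pre_code, post = post_code,
    Esyn = vapply(cfg$connections, `[[`, 0, "E_syn"),
    Uinc = getc("U_inc"), tauf = getc("tau_f"), taur = getc("tau_r"),
    taud = getc("tau_d"), w = getc("w"), gmax = getc("g_syn_max")
  )
}

#' Run the coupled CBRD network simulation
#'
#' Evolves one refractory-density grid per simulated population, coupled by
#' rate-driven Tsodyks-Markram synapses; external-input populations enter as
#' prescribed von Mises rate drives. The solver is deterministic and every
#' operation is differentiable with respect to the trainable parameters (see
#' [fit_network()]).
#'
#' @param cfg a [network_config()].
#' @param duration_ms simulated time (ms).
#' @param theta_hz optional theta frequency (Hz) overriding the drive
#'   profiles' own frequency (used by [frequency_sweep()]).
#' @param drives optional named list of [rate_trace()] drives for external
#'   populations; defaults to each population's target profile.
#' @param dt time step (ms).
#' @param N age-grid points per population.
#' @param dt_star age resolution (ms).
#' @param no_stp freeze short-term plasticity (ablation variant).
#' @param record_conductances keep per-connection conductance traces.
#' @return an object of class `cbrd_run`: `times` (ms), `rates` (matrix,
#'   spikes/s, one column per simulated population), `conductances` (matrix,
#'   mS/cm^2, one column per connection, or `NULL`), `mass` (per-step density
#'   normalization `sum(rho) dt_star` per population), `connections`
#'   (data.frame pre/post/E_syn), `omega_theta`, `cfg`.
#' @export
run_cbrd <- function(cfg, duration_ms, theta_hz = NULL, drives = NULL,
                     dt = 0.1, N = 400, dt_star = 0.5, no_stp = FALSE,
                     record_conductances = TRUE) {
  stopifnot(inherits(cfg, "network_config"), duration_ms > 0)
  if (dt / dt_star > 1 + 1e-12) {
    stop("CFL violation: dt / dt_star must be <= 1")
  }
  n_steps <- max(1L, as.integer(round(duration_ms / dt)))
  times <- seq_len(n_steps) * dt
  dm <- drives_matrix(cfg, times, theta_hz, drives)
  a <- cfg_arrays(cfg)
  res <- cbrd_forward_cpp(
    n_steps, dt, as.integer(N), dt_star,
    a$Cm, a$gL, a$EL, a$VT, a$Vreset, a$sigma, a$refr, a$Iext,
    as.integer(a$pre), as.integer(a$post), a$Esyn,
    a$Uinc, a$tauf, a$taur, a$taud, a$w, a$gmax,
    dm, isTRUE(no_stp), isTRUE(record_conductances))
  rates <- res$nu * 1000
  colnames(rates) <- a$sim
  g <- NULL
  if (record_conductances && cfg$M > 0) {
    g <- res$g
    colnames(g) <- vapply(cfg$connections, function(cn) {
      paste(cn$pre, cn$post, sep = "->")
    }, "")
  }
  omega <- theta_hz
  if (is.null(omega)) {
    tg <- cfg$populations[[1]]$target
    omega <- if (!is.null(tg)) tg$omega_theta else 7
  }
  mass <- res$mass
  colnames(mass) <- a$sim
  structure(
    list(times = times, rates = rates, conductances = g, mass = mass,
         connections = data.frame(
           pre = vapply(cfg$connections, `[[`, "", "pre"),
           post = vapply(cfg$connections, `[[`, "", "post"),
           E_syn = a$Esyn),
         omega_theta = omega, dt = dt, cfg = cfg, engine = "cbrd"),
    class = "cbrd_run"
  )
}

#' @export
print.cbrd_run <- function(x, ...) {
  cat(sprintf(
    "cbrd_run: %d populations, %.0f ms at dt = %g ms (theta %g Hz)\n",
    ncol(x$rates), max(x$times), x$dt, x$omega_theta))
  mr <- colMeans(x$rates)
  for (nm in colnames(x$rates)) {
    cat(sprintf("  %-8s mean rate %7.2f spikes/s\n", nm, mr[[nm]]))
  }
  invisible(x)
}

#' Extract one population's rate trace from a simulation run
#'
#' @param run a `cbrd_run` or `mc_run` object.
#' @param population population name.
#' @return a [rate_trace()] (spikes/s).
#' @export
get_rate_trace <- function(run, population) {
  stopifnot(population %in% colnames(run$rates))
  rate_trace(run$times, pmax(run$rates[, population], 0),
             population = population, omega_theta = run$omega_theta)
}
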