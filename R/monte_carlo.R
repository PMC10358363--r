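#' Population rate from a spike count
#'
#' The instantaneous ensemble firing-rate estimator `nu = n_fired / (N dt)`.
#'
#' @param n_fired number of neurons that fired in the step.
#' @param N ensemble size, `>= 1`.
#' @param dt step length (ms), `> 0`.
#' @return rate in spikes/ms (multiply by 1000 for spikes/s).
#' @export
population_rate <- function(n_fired, N, dt) {
  stopifnot(N >= 1, dt > 0)
  n_fired / (N * dt)
}

#' Causal boxcar smoothing of a rate series
#'
#' The raw ensemble estimator at `N = 4000`, `dt = 0.1` ms is very noisy;
#' plots and circular statistics use a short causal boxcar average.
#'
#' @param rates numeric vector.
#' @param width_ms smoothing window (ms).
#' @param dt sample step (ms).
#' @return smoothed vector, same length.
#' @export
smooth_rates <- function(rates, width_ms = 2, dt = 0.1) {
  k <- max(1L, as.integer(round(width_ms / dt)))
  if (k == 1L) return(rates)
  cs <- cumsum(rates)
  lag <- c(rep(0, k), cs[seq_len(length(rates) - k)])
  denom <- pmin(seq_along(rates), k)
  (cs - lag) / denom
}

#' Run the Monte Carlo network simulation
#'
#' Direct stochastic simulation of the network with a finite leaky
#' integrate-and-fire ensemble per simulated population (stochastic Heun
#' integration by default), mean-field Tsodyks-Markram synapses driven by the
#' instantaneous population rate, and external inputs realized as
#' inhomogeneous Poisson generators. Serves as the independent validation
#' oracle for [run_cbrd()].
#'
#' The membrane noise is scaled so that `sigma_m` is the stationary
#' subthreshold voltage dispersion (`dV = sigma_m sqrt(2 dt / tau_M) xi`),
#' the convention assumed by the density solver's hazard function. During the
#' absolute refractory period neurons integrate but cannot fire, so no
#' interspike interval is ever shorter than the refractory period.
#'
#' `w` is interpreted as the pathway's total connection-density coefficient,
#' identical in both engines, so a parameter set fitted with the density
#' solver can be validated unchanged. Set `apply_connection_prob = TRUE` to
#' scale `w` by `cfg$mc_connection_prob` instead.
#'
#' @param cfg a [network_config()].
#' @param duration_ms simulated time (ms).
#' @param theta_hz optional theta frequency override for the drives.
#' @param drives optional named list of [rate_trace()] for external inputs.
#' @param n_per_pop neurons per simulated population (default 4000).
#' @param n_generators Poisson generators per external input.
#' @param seed optional integer seed.
#' @param dt time step (ms).
#' @param method `"heun"` (stochastic Heun) or `"euler"` (Euler-Maruyama).
#' @param no_stp freeze short-term plasticity.
#' @param apply_connection_prob multiply `w` by `cfg$mc_connection_prob`.
#' @param raster_max record spike times for at most this many neurons per
#'   population (0 disables the raster).
#' @param smooth_ms causal boxcar width (ms) for the smoothed rates.
#' @return an object of class `mc_run`: `times`, `rates` (smoothed,
#'   spikes/s), `rates_raw` (unsmoothed), `counts`, `raster` (data.frame
#'   `population`, `neuron_id`, `spike_time_ms`), `drive_rates` (realized
#'   generator rates, spikes/s), `omega_theta`.
#' @export
run_mc <- function(cfg, duration_ms, theta_hz = NULL, drives = NULL,
                   n_per_pop = 4000, n_generators = 4000, seed = NULL,
                   dt = 0.1, method = c("heun", "euler"), no_stp = FALSE,
                   apply_connection_prob = FALSE, raster_max = 1000,
                   smooth_ms = 2) {
  stopifnot(inherits(cfg, "network_config"), duration_ms > 0, n_per_pop >= 1)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- max(1L, as.integer(round(duration_ms / dt)))
  times <- seq_len(n_steps) * dt
  dm <- drives_matrix(cfg, times, theta_hz, drives)
  a <- cfg_arrays(cfg)
  w_scale <- if (apply_connection_prob) cfg$mc_connection_prob else 1
  res <- mc_forward_cpp(
    n_steps, dt, as.integer(n_per_pop),
    a$Cm, a$gL, a$EL, a$VT, a$Vreset, a$sigma, a$refr, a$Iext,
    as.integer(a$pre), as.integer(a$post), a$Esyn,
    a$Uinc, a$tauf, a$taur, a$taud, a$w, a$gmax,
    dm, as.integer(n_generators), method == "heun", isTRUE(no_stp),
    w_scale, as.integer(raster_max))
  raw <- res$counts / (n_per_pop * dt) * 1000 # spikes/s
  colnames(raw) <- a$sim
  sm <- apply(raw, 2, smooth_rates, width_ms = smooth_ms, dt = dt)
  colnames(sm) <- a$sim
  raster <- data.frame(
    population = if (length(res$raster_pop)) a$sim[res$raster_pop] else character(0),
    neuron_id = res$raster_id,
    spike_time_ms = res$raster_time)
  dr <- res$drive_rates * 1000
  if (ncol(dr) > 0) colnames(dr) <- a$ext
  omega <- theta_hz
  if (is.null(omega)) {
    tg <- cfg$populations[[1]]$target
    omega <- if (!is.null(tg)) tg$omega_theta else 7
  }
  structure(
    list(times = times, rates = sm, rates_raw = raw, counts = res$counts,
         raster = raster, drive_rates = dr, omega_theta = omega, dt = dt,
         n_per_pop = n_per_pop, engine = "mc"),
    class = "mc_run"
  )
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf(
    "mc_run: %d populations x %d neurons, %.0f ms at dt = %g ms (theta %g Hz)\n",
    ncol(x$rates), x$n_per_pop, max(x$times), x$dt, x$omega_theta))
  mr <- colMeans(x$rates)
  for (nm in colnames(x$rates)) {
    cat(sprintf("  %-8s mean rate %7.2f spikes/s\n", nm, mr[[nm]]))
  }
  invisible(x)
}

#' Write a Monte Carlo raster to CSV
#'
#' @param run an `mc_run`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(run, path) {
  stopifnot(inherits(run, "mc_run"))
  write.csv(run$raster, path, row.names = FALSE)
  invisible(path)
}
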