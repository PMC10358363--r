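#' Von Mises concentration from resultant vector length
#'
#' Converts the circular-statistics resultant length R ("ray length") into the
#' von Mises concentration parameter kappa with the standard three-branch
#' approximation (Mardia & Jupp): a polynomial for small R, a rational
#' correction for intermediate R, and the large-R asymptote.
#'
#' @param R numeric vector of resultant lengths, each in `[0, 1)`.
#' @return numeric vector of concentrations, `kappa >= 0`.
#' @examples
#' kappa_from_R(c(0, 0.3, 0.9))
#' @export
kappa_from_R <- function(R) {
  if (!is.numeric(R) || any(!is.finite(R))) {
    stop("R must be finite numeric")
  }
  if (any(R < 0 | R >= 1)) {
    stop("R must lie in [0, 1)")
  }
  kappa <- numeric(length(R))
  lo <- R < 0.53
  mid <- R >= 0.53 & R < 0.85
  hi <- R >= 0.85
  kappa[lo] <- 2 * R[lo] + R[lo]^3 + 5 / 6 * R[lo]^5
  kappa[mid] <- -0.4 + 1.39 * R[mid] + 0.43 / (1 - R[mid])
  kappa[hi] <- 1 / (3 * R[hi] - 4 * R[hi]^2 + R[hi]^3)
  kappa
}

#' Theta-profile parameter set
#'
#' Bundles the parameters of a theta-modulated von Mises firing-rate profile:
#' mean rate, modulation depth (as resultant length R), theta frequency and
#' preferred (peak) phase. The concentration kappa is derived from R via
#' [kappa_from_R()].
#'
#' @param FR_mean mean population firing rate (spikes/s), `>= 0`.
#' @param R resultant vector length in `[0, 1)`; 0 means unmodulated.
#' @param omega_theta theta frequency (Hz).
#' @param phi preferred phase (rad) in `(-pi, pi]`; the profile peaks there.
#' @return an object of class `theta_profile_params`.
#' @export
theta_profile_params <- function(FR_mean, R, omega_theta = 7, phi = 0) {
  stopifnot(is.numeric(FR_mean), FR_mean >= 0, is.numeric(omega_theta),
            omega_theta > 0)
  if (R < 0 || R >= 1) stop("R must lie in [0, 1)")
  if (phi <= -pi - 1e-9 || phi > pi + 1e-9) {
    stop("phi must lie in (-pi, pi]")
  }
  structure(
    list(FR_mean = FR_mean, R = R, omega_theta = omega_theta, phi = phi,
         kappa = kappa_from_R(R)),
    class = "theta_profile_params"
  )
}

#' @export
print.theta_profile_params <- function(x, ...) {
  cat(sprintf(
    "theta profile: FR_mean = %g spikes/s, R = %g (kappa = %.4g), %g Hz, phi = %g rad\n",
    x$FR_mean, x$R, x$kappa, x$omega_theta, x$phi))
  invisible(x)
}

#' Population rate trace
#'
#' A time series of population firing rate with its theta-phase metadata.
#' Rates are stored in spikes/s (the user-facing unit); engine internals use
#' spikes/ms and convert at the boundary.
#'
#' @param times sample times (ms), strictly increasing, uniform step.
#' @param rates firing rates (spikes/s), nonnegative, same length as `times`.
#' @param population population name.
#' @param omega_theta theta frequency (Hz) used to map time to phase.
#' @return an object of class `rate_trace`.
#' @export
rate_trace <- function(times, rates, population = "pop", omega_theta = 7) {
  stopifnot(length(times) == length(rates), length(times) >= 1)
  if (any(rates < 0)) stop("rates must be nonnegative")
  dt <- diff(times)
  if (length(dt) > 0) {
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (diff(range(dt)) > 1e-8 * max(dt)) stop("times must be uniformly spaced")
  }
  structure(
    list(times = as.numeric(times), rates = as.numeric(rates),
         population = population, omega_theta = omega_theta),
    class = "rate_trace"
  )
}

#' @export
print.rate_trace <- function(x, ...) {
  cat(sprintf(
    "rate_trace '%s': %d samples, %.1f..%.1f ms, mean %.3g spikes/s (theta %g Hz)\n",
    x$population, length(x$times), min(x$times), max(x$times),
    mean(x$rates), x$omega_theta))
  invisible(x)
}

#' @export
as.data.frame.rate_trace <- function(x, ...) {
  data.frame(time_ms = x$times, rate_spikes_per_s = x$rates,
             population = x$population)
}

#' Write a rate trace to CSV
#'
#' @param x a `rate_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rate_trace <- function(x, path) {
  stopifnot(inherits(x, "rate_trace"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Generate a von Mises theta-modulated rate profile
#'
#' Evaluates `FR(t) = FR_mean / I0(kappa) * exp(kappa * cos(2 pi omega t - phi))`
#' on a time grid. The normalization by the modified Bessel function `I0`
#' guarantees that the average over an integer number of theta cycles equals
#' `FR_mean`.
#'
#' @param params a [theta_profile_params()] object.
#' @param times sample times (ms), uniform grid.
#' @param population name attached to the returned trace.
#' @return a [rate_trace()] in spikes/s.
#' @export
rate_profile <- function(params, times, population = "pop") {
  stopifnot(inherits(params, "theta_profile_params"))
  kappa <- params$kappa
  phase <- 2 * pi * params$omega_theta * times / 1000 - params$phi
  rates <- params$FR_mean / besselI(kappa, 0) * exp(kappa * cos(phase))
  rate_trace(times, rates, population = population,
             omega_theta = params$omega_theta)
}

#' Default theta-phase target registry
#'
#' The reference target-profile parameters for the ten populations of the CA1
#' microcircuit model: three external excitatory inputs (ca3pyr, ca1pyr, ec3)
#' and seven interneuron classes. Each entry holds the resultant length R,
#' theta frequency (Hz), mean rate (spikes/s) and preferred phase (rad).
#'
#' @param population optional single population name; if given, that entry is
#'   returned and an unknown name is an error.
#' @return a named list of [theta_profile_params()] (or a single entry).
#' @export
target_registry <- function(population = NULL) {
  tab <- list(
    ca3pyr = c(R = 0.3, omega = 7.0, FR_mean = 0.5,  phi = 1.58),
    ca1pyr = c(R = 0.2, omega = 7.0, FR_mean = 0.5,  phi = 3.14),
    ec3    = c(R = 0.2, omega = 7.0, FR_mean = 1.5,  phi = -1.57),
    pvbas  = c(R = 0.3, omega = 7.0, FR_mean = 24,   phi = 1.57),
    olm    = c(R = 0.3, omega = 7.0, FR_mean = 30,   phi = 3.14),
    cckbas = c(R = 0.3, omega = 7.0, FR_mean = 9.0,  phi = -1.57),
    bis    = c(R = 0.3, omega = 7.0, FR_mean = 27.0, phi = 3.14),
    aac    = c(R = 0.3, omega = 7.0, FR_mean = 29.0, phi = 0.0),
    ivy    = c(R = 0.3, omega = 7.0, FR_mean = 4.0,  phi = -1.57),
    ngf    = c(R = 0.3, omega = 7.0, FR_mean = 8.0,  phi = 0.0)
  )
  reg <- lapply(tab, function(v) {
    theta_profile_params(FR_mean = v[["FR_mean"]], R = v[["R"]],
                         omega_theta = v[["omega"]], phi = v[["phi"]])
  })
  if (is.null(population)) return(reg)
  if (!population %in% names(reg)) {
    stop(sprintf("unknown population '%s'", population))
  }
  reg[[population]]
}

#' Inhomogeneous Poisson spike generation by thinning
#'
#' Realizes `n_generators` independent inhomogeneous Poisson spike trains whose
#' rate follows a [rate_trace()]. Uses thinning against the peak rate, which is
#' exact for bounded rate functions.
#'
#' @param trace a [rate_trace()] (spikes/s).
#' @param n_generators number of independent generators, `>= 1`.
#' @param seed optional integer seed for reproducibility.
#' @return a list of numeric vectors of spike times (ms), one per generator.
#' @export
poisson_spikes <- function(trace, n_generators = 1, seed = NULL) {
  stopifnot(inherits(trace, "rate_trace"), n_generators >= 1)
  if (!is.null(seed)) set.seed(seed)
  peak <- max(trace$rates) / 1000 # spikes/ms
  t0 <- trace$times[1]
  t1 <- trace$times[length(trace$times)]
  if (peak <= 0) {
    return(replicate(n_generators, numeric(0), simplify = FALSE))
  }
  lapply(seq_len(n_generators), function(g) {
    n_cand <- stats::rpois(1, peak * (t1 - t0))
    if (n_cand == 0) return(numeric(0))
    tt <- sort(runif(n_cand, t0, t1))
    r <- stats::approx(trace$times, trace$rates, xout = tt, rule = 2)$y / 1000
    tt[runif(n_cand) < r / peak]
  })
}

#' Circular phase of time points
#'
#' Maps time to theta phase, `wrap(2 pi omega t)` into `(-pi, pi]`, with phase
#' zero at the peak of the reference cosine.
#'
#' @param times_ms time points (ms).
#' @param omega_theta theta frequency (Hz).
#' @return phases (rad) in `(-pi, pi]`.
#' @export
theta_phase <- function(times_ms, omega_theta) {
  wrap_phase(2 * pi * omega_theta * times_ms / 1000)
}

#' Wrap angles into (-pi, pi]
#' @param x angles (rad).
#' @return wrapped angles.
#' @export
wrap_phase <- function(x) {
  y <- x %% (2 * pi)
  y[y > pi] <- y[y > pi] - 2 * pi
  y
}
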