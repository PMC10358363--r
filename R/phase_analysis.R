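#' Rate-weighted circular statistics of a trace
#'
#' Treats the firing rate as a weight over theta phase
#' `theta(t) = wrap(2 pi omega t)` and computes the first trigonometric
#' moment: `mean_phase = arg(sum r e^{i theta})`,
#' `R = |sum r e^{i theta}| / sum r`, plus the time-averaged rate. The trace
#' should cover an integer number of theta cycles; the statistics are then
#' invariant to adding whole cycles.
#'
#' @param trace a [rate_trace()] (spikes/s), not all zero.
#' @return an object of class `circular_summary`: `mean_phase` (rad, in
#'   `(-pi, pi]`), `R` in `[0, 1]`, `mean_rate` (spikes/s).
#' @export
circular_stats <- function(trace) {
  stopifnot(inherits(trace, "rate_trace"))
  r <- trace$rates
  if (all(r == 0)) stop("all-zero trace: phase undefined")
  ph <- theta_phase(trace$times, trace$omega_theta)
  z <- sum(r * exp(1i * ph))
  structure(
    list(mean_phase = Arg(z), R = Mod(z) / sum(r), mean_rate = mean(r)),
    class = "circular_summary"
  )
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("circular_summary: mean_phase = %.4f rad, R = %.4f, mean_rate = %.4g spikes/s\n",
              x$mean_phase, x$R, x$mean_rate))
  invisible(x)
}

#' Trim a trace to an integer number of theta cycles
#'
#' Drops an initial burn-in and keeps the largest whole number of cycles
#' that fits in the remainder.
#'
#' @param trace a [rate_trace()].
#' @param burn_ms initial time to discard (ms).
#' @return a [rate_trace()].
#' @export
trim_to_cycles <- function(trace, burn_ms = 0) {
  cycle <- 1000 / trace$omega_theta
  keep <- trace$times > burn_ms
  tt <- trace$times[keep]
  rr <- trace$rates[keep]
  n_cyc <- floor((tt[length(tt)] - tt[1]) * trace$omega_theta / 1000 + 1e-9)
  if (n_cyc < 1) stop("trace shorter than one theta cycle after burn-in")
  stop_t <- tt[1] + n_cyc * cycle
  keep2 <- tt <= stop_t + 1e-9
  rate_trace(tt[keep2], rr[keep2], population = trace$population,
             omega_theta = trace$omega_theta)
}

#' Decompose synaptic conductances by source and polarity
#'
#' Groups the per-connection conductance traces of a [run_cbrd()] output by
#' postsynaptic population, presynaptic source and polarity (excitatory:
#' `E_syn > -30` mV; inhibitory otherwise), and forms the summed excitatory
#' and inhibitory conductances and their ratio.
#'
#' @param run a `cbrd_run` with recorded conductances.
#' @return named list (one entry per simulated population) of objects of
#'   class `conductance_decomposition`: `times`, `components` (matrix, one
#'   column per presynaptic source), `excitatory` (logical per component),
#'   `sum_exc`, `sum_inh`, `ei_ratio` (NA where the inhibitory sum is zero).
#' @export
decompose_conductances <- function(run) {
  stopifnot(inherits(run, "cbrd_run"))
  if (is.null(run$conductances)) {
    stop("run has no conductance traces; use record_conductances = TRUE")
  }
  cn <- run$connections
  out <- list()
  for (pop in colnames(run$rates)) {
    sel <- which(cn$post == pop)
    if (length(sel) == 0) next
    comp <- run$conductances[, sel, drop = FALSE]
    colnames(comp) <- cn$pre[sel]
    exc <- cn$E_syn[sel] > -30
    sum_exc <- if (any(exc)) rowSums(comp[, exc, drop = FALSE]) else
      numeric(nrow(comp))
    sum_inh <- if (any(!exc)) rowSums(comp[, !exc, drop = FALSE]) else
      numeric(nrow(comp))
    ei <- ifelse(sum_inh > 1e-12, sum_exc / sum_inh, NA_real_)
    out[[pop]] <- structure(
      list(population = pop, times = run$times, components = comp,
           excitatory = exc, sum_exc = sum_exc, sum_inh = sum_inh,
           ei_ratio = ei, omega_theta = run$omega_theta),
      class = "conductance_decomposition")
  }
  out
}

#' @export
print.conductance_decomposition <- function(x, ...) {
  cat(sprintf(
    "conductance_decomposition '%s': %d sources (%d exc, %d inh), mean E/I = %.3g\n",
    x$population, ncol(x$components), sum(x$excitatory), sum(!x$excitatory),
    mean(x$ei_ratio, na.rm = TRUE)))
  invisible(x)
}

circular_peak <- function(times, values, omega_theta, argmax = FALSE) {
  if (max(values) - min(values) < 1e-12) stop("flat trace: peak undefined")
  ph <- theta_phase(times, omega_theta)
  if (argmax) return(ph[which.max(values)])
  v <- values - min(values)
  Arg(sum(v * exp(1i * ph)))
}

circ_diff <- function(a, b) wrap_phase(a - b)

#' Phase alignment of conductance and rate peaks
#'
#' Locates the theta phase of the excitatory conductance peak, the
#' inhibitory conductance peak and the firing-rate peak (by the circular
#' first trigonometric moment, robust to numerical ripple; set
#' `argmax = TRUE` for the literal maximum) and returns their pairwise
#' circular differences.
#'
#' @param decomp a `conductance_decomposition` for one population.
#' @param rate a [rate_trace()] for the same population.
#' @param argmax use the literal argmax instead of the circular moment.
#' @return list with `phase_exc`, `phase_inh`, `phase_rate` (rad) and the
#'   circular lags `exc_minus_inh`, `exc_minus_rate`, `inh_minus_rate`.
#' @export
peak_alignment <- function(decomp, rate, argmax = FALSE) {
  stopifnot(inherits(decomp, "conductance_decomposition"),
            inherits(rate, "rate_trace"))
  pe <- circular_peak(decomp$times, decomp$sum_exc, decomp$omega_theta, argmax)
  pi_ <- circular_peak(decomp$times, decomp$sum_inh, decomp$omega_theta, argmax)
  pr <- circular_peak(rate$times, rate$rates, rate$omega_theta, argmax)
  list(phase_exc = pe, phase_inh = pi_, phase_rate = pr,
       exc_minus_inh = circ_diff(pe, pi_),
       exc_minus_rate = circ_diff(pe, pr),
       inh_minus_rate = circ_diff(pi_, pr))
}

#' Theta-frequency generalization sweep
#'
#' Reruns the density solver at several theta frequencies, changing only the
#' frequency of the external drive profiles (all fitted parameters fixed),
#' and summarizes each population's activity by rate-weighted circular
#' statistics on the post-burn-in window.
#'
#' @param cfg a [network_config()] (with fitted parameters applied).
#' @param frequencies theta frequencies (Hz), e.g. `c(4, 7, 12)`.
#' @param burn_cycles cycles discarded before statistics.
#' @param analysis_cycles whole cycles analyzed.
#' @param ... passed to [run_cbrd()] (`dt`, `N`, `dt_star`, `no_stp`).
#' @return data.frame with columns `population`, `frequency`, `mean_rate`,
#'   `mean_phase`, `R`.
#' @export
frequency_sweep <- function(cfg, frequencies, burn_cycles = 2,
                            analysis_cycles = 2, ...) {
  stopifnot(length(frequencies) >= 1, all(frequencies > 0))
  rows <- list()
  for (f in frequencies) {
    cycle <- 1000 / f
    run <- run_cbrd(cfg, (burn_cycles + analysis_cycles) * cycle,
                    theta_hz = f, record_conductances = FALSE, ...)
    win <- run$times > burn_cycles * cycle
    for (pop in colnames(run$rates)) {
      tr <- rate_trace(run$times[win], pmax(run$rates[win, pop], 0),
                       population = pop, omega_theta = f)
      cs <- circular_stats(tr)
      rows[[length(rows) + 1]] <- data.frame(
        population = pop, frequency = f, mean_rate = cs$mean_rate,
        mean_phase = cs$mean_phase, R = cs$R)
    }
  }
  do.call(rbind, rows)
}

#' Phase histogram of a rate trace
#'
#' Bins the rate-weighted activity over theta phase (default 36 bins over
#' `(-pi, pi]`), as a rate-weighted density or a plain histogram of sample
#' counts.
#'
#' @param trace a [rate_trace()].
#' @param n_bins number of phase bins.
#' @param weighted rate-weighted (default) or unweighted.
#' @return data.frame with `phase_mid` (rad) and `density` (normalized to
#'   integrate to 1 over the circle).
#' @export
phase_histogram <- function(trace, n_bins = 36, weighted = TRUE) {
  stopifnot(inherits(trace, "rate_trace"), n_bins >= 4)
  ph <- theta_phase(trace$times, trace$omega_theta)
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- cut(ph, breaks, include.lowest = TRUE, labels = FALSE)
  w <- if (weighted) trace$rates else rep(1, length(ph))
  dens <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), 0)
  width <- 2 * pi / n_bins
  dens <- dens / (sum(dens) * width)
  data.frame(phase_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             density = dens)
}
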