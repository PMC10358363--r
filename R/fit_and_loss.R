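param_fields <- c("U_inc", "tau_f", "tau_r", "tau_d", "w", "g_syn_max")

#' Flatten the trainable parameters of a network
#'
#' Six Tsodyks-Markram parameters per connection followed by one external
#' current per simulated population, as a named numeric vector (natural
#' units). The inverse of [apply_parameters()].
#'
#' @param cfg a [network_config()].
#' @return named numeric vector of length `6 M + K`.
#' @export
flatten_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  out <- numeric(0)
  for (cn in cfg$connections) {
    v <- unlist(cn$params[param_fields])
    names(v) <- paste(cn$pre, cn$post, param_fields, sep = ".")
    out <- c(out, v)
  }
  sim <- simulated_populations(cfg)
  iext <- vapply(cfg$populations[sim], `[[`, 0, "I_ext")
  names(iext) <- paste0("I_ext.", sim)
  c(out, iext)
}

#' Apply a flat parameter vector to a network
#'
#' @param cfg a [network_config()].
#' @param theta numeric vector as produced by [flatten_parameters()] (names
#'   are ignored; order is positional).
#' @return the updated [network_config()].
#' @export
apply_parameters <- function(cfg, theta) {
  stopifnot(inherits(cfg, "network_config"),
            length(theta) == 6 * cfg$M + cfg$K)
  idx <- 0
  for (j in seq_along(cfg$connections)) {
    for (f in param_fields) {
      idx <- idx + 1
      cfg$connections[[j]]$params[[f]] <- unname(theta[idx])
    }
  }
  for (nm in simulated_populations(cfg)) {
    idx <- idx + 1
    cfg$populations[[nm]]$I_ext <- unname(theta[idx])
  }
  cfg
}

#' Simulation loss between rate traces
#'
#' Sum over populations and time points of squared differences of
#' `log(rate + 1)`, with rates in spikes/s:
#' `L = sum_k sum_t (log(target + 1) - log(simulated + 1))^2`.
#'
#' @param simulated matrix (time x population, spikes/s) or list of
#'   [rate_trace()].
#' @param target same shape as `simulated`.
#' @return nonnegative scalar; zero iff the traces are identical.
#' @export
simulation_loss <- function(simulated, target) {
  s <- as_rate_matrix(simulated)
  t <- as_rate_matrix(target)
  stopifnot(all(dim(s) == dim(t)))
  if (any(s < 0) || any(t < 0)) stop("rates must be nonnegative")
  sum((log1p(t) - log1p(s))^2)
}

as_rate_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "rate_trace")) return(matrix(x$rates, ncol = 1))
  if (is.list(x)) {
    return(do.call(cbind, lapply(x, function(tr) tr$rates)))
  }
  stop("expected a matrix, rate_trace, or list of rate_trace")
}

#' Logarithmic barrier loss on synapse parameters
#'
#' Keeps every trainable synapse parameter strictly inside its bounds: each
#' connection contributes `-0.001 ln(100 theta)` for `g_syn_max`, `tau_r`,
#' `tau_f`, `tau_d`, `U_inc`, `w` and `1 - U_inc`. The loss diverges to
#' `+Inf` as any parameter approaches a bound; a parameter at or beyond a
#' bound is a domain error.
#'
#' @param cfg a [network_config()], or a numeric vector from
#'   [flatten_parameters()] together with the number of connections `M`.
#' @param weight barrier weight (default 0.001).
#' @param scale barrier scale (default 100).
#' @param M number of connections; required when `cfg` is a plain vector.
#' @return scalar.
#' @export
barrier_loss <- function(cfg, weight = 0.001, scale = 100, M = NULL) {
  if (inherits(cfg, "network_config")) {
    theta <- flatten_parameters(cfg)
    M <- cfg$M
  } else {
    theta <- cfg
    if (is.null(M)) stop("M must be given when cfg is a parameter vector")
  }
  if (M == 0) return(0)
  con <- matrix(theta[seq_len(6 * M)], nrow = 6)
  rownames(con) <- param_fields
  vals <- c(con["g_syn_max", ], con["tau_r", ], con["tau_f", ],
            con["tau_d", ], con["U_inc", ], con["w", ],
            1 - con["U_inc", ])
  if (any(vals <= 0)) {
    stop("barrier domain error: a parameter is at or beyond its bound")
  }
  sum(-weight * log(scale * vals))
}

barrier_grad <- function(theta, M, weight = 0.001) {
  g <- numeric(length(theta))
  if (M == 0) return(g)
  for (j in seq_len(M)) {
    o <- (j - 1) * 6
    Uinc <- theta[o + 1]
    # d/dtheta of -w ln(100 theta) = -w / theta
    g[o + 1] <- -weight / Uinc + weight / (1 - Uinc) # U_inc and 1 - U_inc
    g[o + 2] <- -weight / theta[o + 2]               # tau_f
    g[o + 3] <- -weight / theta[o + 3]               # tau_r
    g[o + 4] <- -weight / theta[o + 4]               # tau_d
    g[o + 5] <- -weight / theta[o + 5]               # w
    g[o + 6] <- -weight / theta[o + 6]               # g_syn_max
  }
  g
}

#' Full optimization loss
#'
#' `L_full = L_simulation + L_barrier`.
#'
#' @param cfg a [network_config()] (for the barrier term).
#' @param simulated,target as in [simulation_loss()].
#' @return scalar.
#' @export
full_loss <- function(cfg, simulated, target) {
  simulation_loss(simulated, target) + barrier_loss(cfg)
}

# target matrix (loss window x K, spikes/s) for the simulated populations
target_matrix <- function(cfg, targets, times) {
  sim <- simulated_populations(cfg)
  if (is.null(targets)) {
    targets <- lapply(cfg$populations[sim], `[[`, "target")
    if (any(vapply(targets, is.null, TRUE))) {
      stop("no targets given and some simulated populations lack target profiles")
    }
  }
  mat <- vapply(sim, function(nm) {
    tg <- targets[[nm]]
    if (is.null(tg)) stop(sprintf("no target for population '%s'", nm))
    if (inherits(tg, "rate_trace")) {
      stats::approx(tg$times, tg$rates, xout = times, rule = 2)$y
    } else {
      rate_profile(tg, times, population = nm)$rates
    }
  }, numeric(length(times)))
  matrix(mat, ncol = length(sim), dimnames = list(NULL, sim))
}

# Unconstrained reparameterization: log for the positive synapse parameters
# (scale-free: a fixed Adam step moves every parameter by the same relative
# amount, whether it is a 5 ms decay or a 500 ms recovery constant), logit
# for U_inc, identity for I_ext. The barrier is still evaluated in natural
# space.
raw_from_natural <- function(theta, M) {
  raw <- theta
  for (j in seq_len(M)) {
    o <- (j - 1) * 6
    raw[o + 1] <- stats::qlogis(theta[o + 1])
    raw[o + 2:6] <- log(theta[o + 2:6])
  }
  raw # I_ext entries stay unconstrained
}

natural_from_raw <- function(raw, M) {
  theta <- raw
  for (j in seq_len(M)) {
    o <- (j - 1) * 6
    theta[o + 1] <- stats::plogis(raw[o + 1])
    theta[o + 2:6] <- exp(pmin(raw[o + 2:6], 30))
  }
  theta
}

chain_to_raw <- function(grad_nat, raw, M) {
  g <- grad_nat
  for (j in seq_len(M)) {
    o <- (j - 1) * 6
    p <- stats::plogis(raw[o + 1])
    g[o + 1] <- grad_nat[o + 1] * p * (1 - p)
    g[o + 2:6] <- grad_nat[o + 2:6] * exp(pmin(raw[o + 2:6], 30))
  }
  g
}

# one differentiable evaluation: L_full value and gradient in natural space
loss_value_grad <- function(cfg, targets, burn_cycles, loss_cycles, theta_hz,
                            dt, N, dt_star, no_stp) {
  omega <- theta_hz
  if (is.null(omega)) {
    tg <- cfg$populations[[1]]$target
    omega <- if (!is.null(tg)) tg$omega_theta else 7
  }
  cycle_ms <- 1000 / omega
  duration <- (burn_cycles + loss_cycles) * cycle_ms
  n_steps <- as.integer(round(duration / dt))
  n_burn <- as.integer(round(burn_cycles * cycle_ms / dt))
  times <- seq_len(n_steps) * dt
  dm <- drives_matrix(cfg, times, theta_hz)
  a <- cfg_arrays(cfg)
  win <- (n_burn + 1):n_steps
  tmat <- target_matrix(cfg, targets, times[win])

  # single call: forward with recording, loss on the window, reverse sweep
  res <- cbrd_adjoint_cpp(
    n_steps, dt, as.integer(N), dt_star,
    a$Cm, a$gL, a$EL, a$VT, a$Vreset, a$sigma, a$refr, a$Iext,
    as.integer(a$pre), as.integer(a$post), a$Esyn,
    a$Uinc, a$tauf, a$taur, a$taud, a$w, a$gmax,
    dm, isTRUE(no_stp), tmat, n_burn)
  L_sim <- res$L_sim

  grad_sim <- numeric(6 * cfg$M + cfg$K)
  for (j in seq_len(cfg$M)) {
    o <- (j - 1) * 6
    grad_sim[o + 1] <- res$dUinc[j]
    grad_sim[o + 2] <- res$dtauf[j]
    grad_sim[o + 3] <- res$dtaur[j]
    grad_sim[o + 4] <- res$dtaud[j]
    grad_sim[o + 5] <- res$dw[j]
    grad_sim[o + 6] <- res$dgmax[j]
  }
  grad_sim[6 * cfg$M + seq_len(cfg$K)] <- res$dIext

  theta <- flatten_parameters(cfg)
  L_bar <- barrier_loss(theta, weight = 0.001, M = cfg$M)
  grad <- grad_sim + barrier_grad(theta, cfg$M)
  list(L_sim = L_sim, L_barrier = L_bar, L_full = L_sim + L_bar,
       grad = grad, grad_sim = grad_sim, rates = res$nu * 1000,
       times = times, window = win, targets = tmat)
}

#' Fit the network parameters by Adam gradient descent
#'
#' Minimizes the full loss (simulation + barrier) over all `6 M + K`
#' trainable parameters with the Adam optimizer (learning rate 0.001,
#' `beta1 = 0.9`, `beta2 = 0.999` by default). Each iteration simulates
#' `burn_cycles + loss_cycles` theta cycles with the density solver and
#' evaluates the loss on the post-burn-in window; gradients come from the
#' solver's reverse-mode adjoint. Parameters are updated in unconstrained
#' space (log for positive parameters, logit for `U_inc`) while the
#' barrier is evaluated in natural space, so bounds can never be overshot.
#'
#' The run is fully deterministic: identical inputs give bitwise-identical
#' loss histories.
#'
#' @param cfg a [network_config()] holding the initial parameter values.
#' @param targets optional named list of [theta_profile_params()] per
#'   simulated population; defaults to the populations' own target profiles.
#' @param n_iterations Adam iterations (0 returns the initial parameters).
#' @param burn_cycles theta cycles discarded before the loss window.
#' @param loss_cycles theta cycles in the loss window.
#' @param theta_hz optional theta frequency override.
#' @param dt,N,dt_star solver resolution, as in [run_cbrd()].
#' @param lr,beta1,beta2,eps Adam settings.
#' @param no_stp fit the frozen-plasticity (ablation) network.
#' @param verbose print the loss every 25 iterations.
#' @return an object of class `fit_result`: `parameters` (named, natural
#'   units), `cfg` (with fitted parameters applied), `loss_history`
#'   (`L_full` per iteration), `sim_loss_history`, `diagnostics`
#'   (per-population mean rate, mean phase and R of the final run, next to
#'   their targets).
#' @export
fit_network <- function(cfg, targets = NULL, n_iterations = 500,
                        burn_cycles = 2, loss_cycles = 2, theta_hz = NULL,
                        dt = 0.1, N = 400, dt_star = 0.5, lr = 0.001,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        no_stp = FALSE, verbose = FALSE) {
  stopifnot(inherits(cfg, "network_config"), n_iterations >= 0)
  theta0 <- flatten_parameters(cfg)
  raw <- raw_from_natural(theta0, cfg$M)
  m <- numeric(length(raw))
  v <- numeric(length(raw))
  loss_history <- numeric(n_iterations)
  sim_history <- numeric(n_iterations)
  cur <- cfg
  for (it in seq_len(n_iterations)) {
    ev <- loss_value_grad(cur, targets, burn_cycles, loss_cycles, theta_hz,
                          dt, N, dt_star, no_stp)
    if (!is.finite(ev$L_full)) {
      stop(sprintf("non-finite loss at iteration %d", it))
    }
    loss_history[it] <- ev$L_full
    sim_history[it] <- ev$L_sim
    g <- chain_to_raw(ev$grad, raw, cfg$M)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^it)
    vhat <- v / (1 - beta2^it)
    raw <- raw - lr * mhat / (sqrt(vhat) + eps)
    cur <- apply_parameters(cfg, natural_from_raw(raw, cfg$M))
    if (verbose && it %% 25 == 0) {
      message(sprintf("iter %4d: L_full = %.5f (L_sim = %.5f)", it,
                      ev$L_full, ev$L_sim))
    }
  }
  theta_fit <- setNames(natural_from_raw(raw, cfg$M), names(theta0))
  cfg_fit <- apply_parameters(cfg, theta_fit)
  diag <- fit_diagnostics(cfg_fit, targets, burn_cycles, loss_cycles,
                          theta_hz, dt, N, dt_star, no_stp)
  structure(
    list(parameters = theta_fit, cfg = cfg_fit,
         loss_history = loss_history, sim_loss_history = sim_history,
         diagnostics = diag, no_stp = no_stp),
    class = "fit_result"
  )
}

fit_diagnostics <- function(cfg, targets, burn_cycles, loss_cycles, theta_hz,
                            dt, N, dt_star, no_stp) {
  omega <- theta_hz
  if (is.null(omega)) {
    tg <- cfg$populations[[1]]$target
    omega <- if (!is.null(tg)) tg$omega_theta else 7
  }
  cycle_ms <- 1000 / omega
  run <- run_cbrd(cfg, (burn_cycles + loss_cycles) * cycle_ms,
                  theta_hz = theta_hz, dt = dt, N = N, dt_star = dt_star,
                  no_stp = no_stp, record_conductances = FALSE)
  win <- run$times > burn_cycles * cycle_ms
  sim <- simulated_populations(cfg)
  if (is.null(targets)) targets <- lapply(cfg$populations[sim], `[[`, "target")
  rows <- lapply(sim, function(nm) {
    tr <- rate_trace(run$times[win], pmax(run$rates[win, nm], 0),
                     population = nm, omega_theta = omega)
    cs <- tryCatch(circular_stats(tr), error = function(e) {
      list(mean_rate = 0, mean_phase = NA_real_, R = NA_real_)
    })
    tg <- targets[[nm]]
    if (inherits(tg, "rate_trace")) {
      tcs <- tryCatch(circular_stats(tg), error = function(e) {
        list(mean_rate = 0, mean_phase = NA_real_, R = NA_real_)
      })
      tg <- list(FR_mean = tcs$mean_rate, phi = tcs$mean_phase, R = tcs$R)
    }
    data.frame(population = nm, mean_rate = cs$mean_rate,
               mean_phase = cs$mean_phase, R = cs$R,
               target_rate = if (is.null(tg)) NA_real_ else tg$FR_mean,
               target_phase = if (is.null(tg)) NA_real_ else tg$phi,
               target_R = if (is.null(tg)) NA_real_ else tg$R)
  })
  do.call(rbind, rows)
}

#' @export
print.fit_result <- function(x, ...) {
  n <- length(x$loss_history)
  cat(sprintf("fit_result: %d iterations%s\n", n,
              if (isTRUE(x$no_stp)) " (no-STP ablation)" else ""))
  if (n > 0) {
    cat(sprintf("  L_full: %.5f -> %.5f (L_sim %.5f -> %.5f)\n",
                x$loss_history[1], x$loss_history[n],
                x$sim_loss_history[1], x$sim_loss_history[n]))
  }
  print(x$diagnostics, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Fit the no-STP (frozen plasticity) ablation network
#'
#' Same optimization as [fit_network()] with synapses whose utilization and
#' resources are frozen (`u = U_inc`, `x = 1`): depression and facilitation
#' are removed while the conductance pathway is preserved.
#'
#' @inheritParams fit_network
#' @param ... passed to [fit_network()].
#' @return a `fit_result`.
#' @export
ablation_no_stp <- function(cfg, targets = NULL, n_iterations = 500, ...) {
  fit_network(cfg, targets = targets, n_iterations = n_iterations,
              no_stp = TRUE, ...)
}

#' Verify adjoint gradients against finite differences
#'
#' Compares the reverse-mode adjoint gradient of the full loss with central
#' finite differences over a chosen parameter subset on a short simulation
#' window.
#'
#' @param cfg a [network_config()].
#' @param targets as in [fit_network()].
#' @param parameters character vector of parameter names (as in
#'   [flatten_parameters()]); default: all of them.
#' @param duration_ms simulation window (ms); split into equal burn-in and
#'   loss halves.
#' @param epsilon relative finite-difference step.
#' @param theta_hz,dt,N,dt_star,no_stp as in [fit_network()].
#' @return list with `table` (per-parameter adjoint, numeric and relative
#'   error) and `max_rel_error`.
#' @export
gradient_check <- function(cfg, targets = NULL, parameters = NULL,
                           duration_ms = 100, epsilon = 1e-4,
                           theta_hz = NULL, dt = 0.1, N = 400, dt_star = 0.5,
                           no_stp = FALSE) {
  omega <- theta_hz
  if (is.null(omega)) {
    tg <- cfg$populations[[1]]$target
    omega <- if (!is.null(tg)) tg$omega_theta else 7
  }
  cycles <- duration_ms / 2 / (1000 / omega)
  ev <- loss_value_grad(cfg, targets, cycles, cycles, theta_hz, dt, N,
                        dt_star, no_stp)
  theta <- flatten_parameters(cfg)
  if (is.null(parameters)) parameters <- names(theta)
  idx <- match(parameters, names(theta))
  if (anyNA(idx)) stop("unknown parameter name(s)")
  f <- function(th) {
    e <- loss_value_grad(apply_parameters(cfg, th), targets, cycles, cycles,
                         theta_hz, dt, N, dt_star, no_stp)
    e$L_full
  }
  fd <- vapply(idx, function(i) {
    h <- epsilon * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, 0)
  adj <- ev$grad[idx]
  denom <- pmax(abs(fd), abs(adj))
  rel <- ifelse(denom < 1e-10, 0, abs(fd - adj) / denom)
  list(table = data.frame(parameter = parameters, adjoint = adj,
                          finite_diff = fd, rel_error = rel),
       max_rel_error = max(rel))
}

#' Evaluate the loss of a configuration without fitting
#'
#' @inheritParams fit_network
#' @return list with `L_sim`, `L_barrier`, `L_full` and the simulated loss
#'   window rates.
#' @export
evaluate_loss <- function(cfg, targets = NULL, burn_cycles = 2,
                          loss_cycles = 2, theta_hz = NULL, dt = 0.1,
                          N = 400, dt_star = 0.5, no_stp = FALSE) {
  ev <- loss_value_grad(cfg, targets, burn_cycles, loss_cycles, theta_hz,
                        dt, N, dt_star, no_stp)
  ev[c("L_sim", "L_barrier", "L_full", "rates", "times", "window",
       "targets")]
}

#' Save / load fitted parameters as JSON
#'
#' @param x a `fit_result` or named parameter vector.
#' @param path JSON file path.
#' @return `path` invisibly for save; a named numeric vector for load.
#' @export
save_parameters <- function(x, path) {
  theta <- if (inherits(x, "fit_result")) x$parameters else x
  jsonlite::write_json(as.list(theta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_parameters
#' @export
load_parameters <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(v)
}

#' Reference fitted parameters for the default network
#'
#' Loads the parameter set shipped with the package, obtained by running
#' [fit_network()] on [default_network()] at 7 Hz (see the package vignette
#' for the optimization settings used).
#'
#' @return named numeric vector compatible with [apply_parameters()].
#' @export
fitted_reference_parameters <- function() {
  load_parameters(system.file("extdata", "fitted_parameters.json",
                              package = "thetafit", mustWork = TRUE))
}
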