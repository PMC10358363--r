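#' Tsodyks-Markram synapse state
#'
#' The per-connection state triple of the rate-driven (mean-field)
#' Tsodyks-Markram model: utilization `u`, recovered resource `x` and active
#' resource `y`. The deactivated fraction is `1 - x - y`. A single state
#' triple serves a whole pathway because the model averages over all synapses
#' between two populations.
#'
#' @param u utilization fraction in `[0, 1]`.
#' @param x recovered fraction, `>= 0`.
#' @param y active fraction, `>= 0`; `x + y <= 1`.
#' @return an object of class `stp_state`.
#' @export
stp_state <- function(u = 0, x = 1, y = 0) {
  if (any(!is.finite(c(u, x, y)))) stop("stp state must be finite")
  if (u < 0 || u > 1) stop("u must be in [0, 1]")
  if (x < 0 || y < 0) stop("x and y must be >= 0")
  if (x + y > 1 + 1e-12) stop("x + y must not exceed 1")
  structure(list(u = u, x = x, y = y), class = "stp_state")
}

#' @export
print.stp_state <- function(x, ...) {
  cat(sprintf("stp_state: u = %.4g, x = %.4g, y = %.4g\n", x$u, x$x, x$y))
  invisible(x)
}

#' One Euler step of the rate-driven Tsodyks-Markram dynamics
#'
#' Advances the synapse state by `dt` under presynaptic population rate
#' `nu_pre`. The jump terms are rate-driven: `du = (-u/tau_f +
#' U_inc (1-u) w nu_pre) dt`, with the post-spike utilization
#' `u_+ = u + U_inc (1-u)` (evaluated at the pre-step `u`) entering the
#' resource transfer terms of `x` and `y`. After the step, `u` is projected
#' onto `[0, 1]` and `(x, y)` onto the simplex `x + y <= 1`, which explicit
#' Euler can otherwise overshoot at large `nu_pre * dt`; the projection is
#' inactive in the smooth regime.
#'
#' With `no_stp = TRUE` the plasticity is frozen (`u = U_inc`, `x = 1`),
#' leaving `dy/dt = -y/tau_d + U_inc w nu_pre`: the conductance pathway is
#' preserved but depression and facilitation are removed.
#'
#' @param state an [stp_state()].
#' @param nu_pre presynaptic population rate (spikes/ms), `>= 0`.
#' @param dt time step (ms), `> 0`.
#' @param params list with `U_inc`, `tau_f`, `tau_r`, `tau_d`, `w`
#'   (`g_syn_max` is ignored here), e.g. `connection_spec(...)$params`.
#' @param no_stp freeze plasticity (ablation variant).
#' @return the updated [stp_state()].
#' @export
stp_step <- function(state, nu_pre, dt, params, no_stp = FALSE) {
  stopifnot(inherits(state, "stp_state"))
  if (!is.finite(nu_pre) || nu_pre < 0) stop("nu_pre must be finite and >= 0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be finite and > 0")
  a <- params$w * nu_pre
  if (no_stp) {
    y <- state$y + dt * (-state$y / params$tau_d + params$U_inc * a)
    # frozen variant: resources are never depleted, so x stays pinned at 1
    # and the simplex bookkeeping of the plastic model does not apply
    return(structure(list(u = params$U_inc, x = 1, y = max(y, 0)),
                     class = "stp_state"))
  }
  u <- state$u; x <- state$x; y <- state$y
  u_plus <- u + params$U_inc * (1 - u)
  u1 <- u + dt * (-u / params$tau_f + params$U_inc * (1 - u) * a)
  x1 <- x + dt * ((1 - x - y) / params$tau_r - u_plus * x * a)
  y1 <- y + dt * (-y / params$tau_d + u_plus * x * a)
  u1 <- min(max(u1, 0), 1)
  x1 <- max(x1, 0)
  y1 <- max(y1, 0)
  s <- x1 + y1
  if (s > 1) {
    x1 <- x1 / s
    y1 <- y1 / s
  }
  stp_state(u = u1, x = x1, y = y1)
}

#' Synaptic conductance from the active resource
#'
#' @param state an [stp_state()].
#' @param g_syn_max maximal conductance (mS/cm^2).
#' @return conductance `g_syn_max * y` (mS/cm^2).
#' @export
synaptic_conductance <- function(state, g_syn_max) {
  stopifnot(inherits(state, "stp_state"), g_syn_max >= 0)
  g_syn_max * state$y
}

#' Synaptic current
#'
#' `I = g (E_syn - V)`; depolarizing currents are positive.
#'
#' @param g conductance (mS/cm^2), `>= 0`.
#' @param E_syn reversal potential (mV).
#' @param V membrane potential (mV).
#' @return current (uA/cm^2).
#' @export
synaptic_current <- function(g, E_syn, V) {
  if (any(g < 0)) stop("conductance must be >= 0")
  g * (E_syn - V)
}
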