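#' Population specification
#'
#' One neuron population of the network. Simulated populations are leaky
#' integrate-and-fire ensembles evolved by the CBRD or Monte Carlo engine;
#' external-input populations are prescribed theta-modulated rate drives and
#' carry a target profile but no membrane dynamics.
#'
#' Default LIF constants (shared by all populations): `C_m = 1` uF/cm^2,
#' `g_L = 0.1` mS/cm^2, `E_L = -60` mV, `V_T = -50` mV, `V_reset = -90` mV,
#' `sigma_m = 0.3` (stationary subthreshold voltage noise SD, mV-scale),
#' absolute refractory period 3 ms.
#'
#' @param name population identifier.
#' @param role `"simulated"` or `"external_input"`.
#' @param C_m membrane capacitance (uF/cm^2).
#' @param g_L leak conductance (mS/cm^2).
#' @param E_L leak reversal potential (mV).
#' @param V_T spike threshold (mV).
#' @param V_reset post-spike reset potential (mV).
#' @param sigma_m noise amplitude; the stationary voltage dispersion scale
#'   entering the hazard function.
#' @param refractory absolute refractory period (ms).
#' @param I_ext external current (uA/cm^2); trainable for simulated
#'   populations.
#' @param target a [theta_profile_params()] (target profile for simulated
#'   populations, drive profile for external inputs), or `NULL`.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(name, role = c("simulated", "external_input"),
                            C_m = 1, g_L = 0.1, E_L = -60, V_T = -50,
                            V_reset = -90, sigma_m = 0.3, refractory = 3,
                            I_ext = 0, target = NULL) {
  role <- match.arg(role)
  if (!is.character(name) || nchar(name) == 0) stop("population needs a name")
  if (role == "simulated") {
    if (V_reset >= V_T) {
      stop(sprintf("population '%s': V_reset must be below V_T", name))
    }
    if (sigma_m <= 0) stop(sprintf("population '%s': sigma_m must be > 0", name))
    if (refractory < 0) {
      stop(sprintf("population '%s': refractory must be >= 0", name))
    }
    if (C_m <= 0 || g_L <= 0) {
      stop(sprintf("population '%s': C_m and g_L must be > 0", name))
    }
  }
  if (!is.null(target) && !inherits(target, "theta_profile_params")) {
    stop(sprintf("population '%s': target must be theta_profile_params", name))
  }
  structure(
    list(name = name, role = role, C_m = C_m, g_L = g_L, E_L = E_L,
         V_T = V_T, V_reset = V_reset, sigma_m = sigma_m,
         refractory = refractory, I_ext = I_ext, target = target),
    class = "population_spec"
  )
}

#' Synaptic connection specification
#'
#' One directed pathway between populations, with its reversal potential and
#' the six trainable Tsodyks-Markram parameters.
#'
#' @param pre presynaptic population name.
#' @param post postsynaptic population name.
#' @param E_syn reversal potential (mV); 0 for AMPA-type excitation, -75 for
#'   GABA-A-type inhibition.
#' @param U_inc release-utilization increment per spike, in (0, 1).
#' @param tau_f facilitation time constant (ms), `> 0`.
#' @param tau_r recovery (from depression) time constant (ms), `> 0`.
#' @param tau_d decay time constant of the active resource (ms), `> 0`.
#' @param w connection-density coefficient (dimensionless), `> 0`.
#' @param g_syn_max maximal synaptic conductance (mS/cm^2), `>= 0`.
#' @return an object of class `connection_spec`.
#' @export
connection_spec <- function(pre, post, E_syn, U_inc = 0.25, tau_f = 100,
                            tau_r = 500, tau_d = 5, w = 1, g_syn_max = 0.05) {
  id <- sprintf("connection %s->%s", pre, post)
  if (U_inc <= 0 || U_inc >= 1) stop(sprintf("%s: U_inc must be in (0, 1)", id))
  if (tau_f <= 0 || tau_r <= 0 || tau_d <= 0) {
    stop(sprintf("%s: tau_f, tau_r, tau_d must be > 0", id))
  }
  if (w <= 0) stop(sprintf("%s: w must be > 0", id))
  if (g_syn_max < 0) stop(sprintf("%s: g_syn_max must be >= 0", id))
  structure(
    list(pre = pre, post = post, E_syn = E_syn,
         params = list(U_inc = U_inc, tau_f = tau_f, tau_r = tau_r,
                       tau_d = tau_d, w = w, g_syn_max = g_syn_max)),
    class = "connection_spec"
  )
}

#' Network configuration
#'
#' Validated container of populations and connections. The reference
#' configuration has seven simulated interneuron populations (pvbas, olm,
#' cckbas, ivy, ngf, bis, aac), three external inputs (ca3pyr, ca1pyr, ec3)
#' and 49 connections.
#'
#' @param populations list of [population_spec()].
#' @param connections list of [connection_spec()].
#' @param mc_connection_prob pairwise connection probability assumed in Monte
#'   Carlo realizations (network-level bookkeeping; see [run_mc()]).
#' @return an object of class `network_config` with fields `populations`
#'   (named list), `connections`, `M` (number of connections) and `K`
#'   (number of simulated populations).
#' @export
network_config <- function(populations, connections = list(),
                           mc_connection_prob = 0.5) {
  stopifnot(length(populations) >= 1)
  for (p in populations) {
    if (!inherits(p, "population_spec")) stop("populations must be population_spec")
  }
  names(populations) <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(names(populations))) {
    stop(sprintf("duplicate population name '%s'",
                 names(populations)[duplicated(names(populations))][1]))
  }
  roles <- vapply(populations, `[[`, "", "role")
  keys <- character(0)
  for (cn in connections) {
    if (!inherits(cn, "connection_spec")) stop("connections must be connection_spec")
    id <- sprintf("connection %s->%s", cn$pre, cn$post)
    if (!cn$pre %in% names(populations)) {
      stop(sprintf("%s: unresolved presynaptic population '%s'", id, cn$pre))
    }
    if (!cn$post %in% names(populations)) {
      stop(sprintf("%s: unresolved postsynaptic population '%s'", id, cn$post))
    }
    if (roles[[cn$post]] == "external_input") {
      stop(sprintf("%s: cannot target an external_input population", id))
    }
    key <- paste(cn$pre, cn$post, sep = "->")
    if (key %in% keys) stop(sprintf("duplicate %s", id))
    keys <- c(keys, key)
  }
  structure(
    list(populations = populations, connections = connections,
         mc_connection_prob = mc_connection_prob,
         M = length(connections), K = sum(roles == "simulated")),
    class = "network_config"
  )
}

#' @export
print.network_config <- function(x, ...) {
  roles <- vapply(x$populations, `[[`, "", "role")
  cat(sprintf(
    "network_config: %d populations (%d simulated, %d external), %d connections, %d trainable parameters\n",
    length(x$populations), x$K, sum(roles == "external_input"), x$M,
    count_trainable_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Six Tsodyks-Markram parameters per connection plus one external current per
#' simulated population: `6 * M + K`. The reference network (M = 49, K = 7)
#' exposes 301 parameters.
#'
#' @param cfg a [network_config()].
#' @return integer count.
#' @export
count_trainable_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  6L * cfg$M + cfg$K
}

#' Names of simulated populations
#' @param cfg a [network_config()].
#' @return character vector in configuration order.
#' @export
simulated_populations <- function(cfg) {
  roles <- vapply(cfg$populations, `[[`, "", "role")
  names(roles)[roles == "simulated"]
}

#' Names of external-input populations
#' @param cfg a [network_config()].
#' @return character vector in configuration order.
#' @export
external_populations <- function(cfg) {
  roles <- vapply(cfg$populations, `[[`, "", "role")
  names(roles)[roles == "external_input"]
}

pop_from_list <- function(rec) {
  target <- NULL
  if (!is.null(rec$target)) {
    target <- theta_profile_params(
      FR_mean = rec$target$FR_mean, R = rec$target$R,
      omega_theta = rec$target$omega_theta, phi = rec$target$phi)
  }
  args <- rec[setdiff(names(rec), "target")]
  args$target <- target
  do.call(population_spec, args)
}

conn_from_list <- function(rec) {
  do.call(connection_spec, rec)
}

#' Load a network configuration from YAML
#'
#' Parses a YAML document with `populations:` and `connections:` sections and
#' returns a validated [network_config()]. Any invariant violation is reported
#' with the offending population or connection identified.
#'
#' @param path YAML file path.
#' @return a [network_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$populations)) stop("config must have a 'populations' section")
  pops <- lapply(doc$populations, pop_from_list)
  conns <- lapply(doc$connections, conn_from_list)
  network_config(pops, conns,
                 mc_connection_prob = doc$mc_connection_prob %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a network configuration to YAML
#'
#' Writes a document that [load_config()] reads back identically (round-trip
#' identity on all fields).
#'
#' @param cfg a [network_config()].
#' @param path output YAML file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "network_config"))
  pops <- lapply(unname(cfg$populations), function(p) {
    rec <- p[c("name", "role", "C_m", "g_L", "E_L", "V_T", "V_reset",
               "sigma_m", "refractory", "I_ext")]
    if (!is.null(p$target)) {
      rec$target <- p$target[c("FR_mean", "R", "omega_theta", "phi")]
    }
    rec
  })
  conns <- lapply(cfg$connections, function(cn) {
    c(list(pre = cn$pre, post = cn$post, E_syn = cn$E_syn), cn$params)
  })
  yaml::write_yaml(
    list(mc_connection_prob = cfg$mc_connection_prob,
         populations = pops, connections = conns),
    path, precision = 15)
  invisible(path)
}

#' The reference CA1 interneuron network
#'
#' Loads the shipped configuration: seven simulated interneuron populations,
#' three external theta-modulated inputs and the 49-edge connectivity, with
#' the documented default initial values of all trainable parameters.
#'
#' @return a [network_config()] with `M = 49`, `K = 7`.
#' @export
default_network <- function() {
  load_config(system.file("extdata", "default_network.yaml",
                          package = "thetafit", mustWork = TRUE))
}

#' The reference 49-edge connectivity
#'
#' Returns the shipped edge list only (a list of [connection_spec()]):
#' excitatory edges (E_syn = 0 mV) from ca3pyr/ca1pyr/ec3 and inhibitory
#' edges (E_syn = -75 mV) between interneuron classes. The list is stored as
#' an editable data file, not code.
#'
#' @return list of 49 [connection_spec()].
#' @export
default_connectivity <- function() {
  default_network()$connections
}
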