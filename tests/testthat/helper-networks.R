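# Small networks built in code for unit tests.

# one LIF population, optional theta-modulated excitatory drive
toy_network <- function(I_ext = 0.9, with_drive = TRUE, U_inc = 0.25,
                        tau_f = 100, tau_r = 500, tau_d = 5, w = 20,
                        g_syn_max = 0.3, drive_FR = 5, drive_R = 0.3) {
  p1 <- population_spec("p1", I_ext = I_ext,
                        target = theta_profile_params(20, 0.3, 7, 1.0))
  if (!with_drive) return(network_config(list(p1)))
  drv <- population_spec("drv", role = "external_input",
                         target = theta_profile_params(drive_FR, drive_R, 7, 0))
  cn <- connection_spec("drv", "p1", E_syn = 0, U_inc = U_inc, tau_f = tau_f,
                        tau_r = tau_r, tau_d = tau_d, w = w,
                        g_syn_max = g_syn_max)
  network_config(list(p1, drv), list(cn))
}

# two coupled populations plus one drive (exercises recurrent adjoint paths)
two_pop_network <- function() {
  p1 <- population_spec("exc_target", I_ext = 0.9,
                        target = theta_profile_params(20, 0.3, 7, 1.0))
  p2 <- population_spec("inh_partner", I_ext = 1.1,
                        target = theta_profile_params(12, 0.3, 7, -1.0))
  drv <- population_spec("drv", role = "external_input",
                         target = theta_profile_params(5, 0.3, 7, 0))
  cns <- list(
    connection_spec("drv", "exc_target", E_syn = 0, w = 20, g_syn_max = 0.3),
    connection_spec("inh_partner", "exc_target", E_syn = -75, w = 5,
                    g_syn_max = 0.1),
    connection_spec("exc_target", "inh_partner", E_syn = -75, w = 5,
                    g_syn_max = 0.1))
  network_config(list(p1, p2, drv), cns)
}

cycle_ms <- function(omega_hz = 7) 1000 / omega_hz
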