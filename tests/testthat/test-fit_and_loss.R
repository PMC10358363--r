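test_that("simulation loss is the summed squared log1p discrepancy", {
  t1 <- matrix(c(1, 2, 3), ncol = 1)
  expect_equal(simulation_loss(t1, t1), 0)
  # single point: target e-1, simulated 0 -> (ln e - ln 1)^2 = 1
  expect_equal(simulation_loss(matrix(0), matrix(exp(1) - 1)), 1)
  # additivity: a uniform discrepancy across two populations doubles it
  s <- matrix(1, nrow = 5, ncol = 1)
  t2 <- matrix(3, nrow = 5, ncol = 1)
  expect_equal(simulation_loss(cbind(s, s), cbind(t2, t2)),
               2 * simulation_loss(s, t2))
  expect_error(simulation_loss(matrix(-1), matrix(1)), "nonnegative")
})

test_that("barrier loss matches its closed form and diverges at bounds", {
  # one connection with all seven barrier arguments equal to 0.01 vanishes;
  # realized through the vector interface (U_inc and 1 - U_inc cannot both
  # be 0.01 in a real connection)
  th <- c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01)
  # order: U_inc, tau_f, tau_r, tau_d, w, g_syn_max; U_inc term appears as
  # both ln(100 U) and ln(100 (1-U))
  b <- barrier_loss(th, M = 1)
  expect_equal(b, -0.001 * (5 * log(1) + log(100 * 0.01) + log(100 * 0.99)))
  # U_inc = 0.5 contributes -0.001 ln(50) twice
  th2 <- c(0.5, 0.01, 0.01, 0.01, 0.01, 0.01)
  expect_equal(barrier_loss(th2, M = 1), -0.002 * log(50), tolerance = 1e-12)
  expect_equal(-0.002 * log(50), -0.007824, tolerance = 1e-4)
  # at or beyond a bound: domain error
  expect_error(barrier_loss(c(1, 1, 1, 1, 1, 1), M = 1), "domain")
  expect_error(barrier_loss(c(0.5, 1, -1, 1, 1, 1), M = 1), "domain")
  # no connections: no barrier
  expect_equal(barrier_loss(network_config(list(population_spec("a")))), 0)
})

test_that("full loss is the exact sum of its components", {
  cfg <- toy_network()
  s <- matrix(1, 3, 1)
  t1 <- matrix(2, 3, 1)
  expect_equal(full_loss(cfg, s, t1),
               simulation_loss(s, t1) + barrier_loss(cfg))
  expect_equal(full_loss(cfg, s, s), barrier_loss(cfg))
})

test_that("barrier gradient points inward near every bound", {
  eps <- 1e-3
  near_low <- c(eps, eps, eps, eps, eps, eps)
  g <- thetafit:::barrier_grad(near_low, 1)
  expect_true(all(g < 0)) # loss decreases as parameters move up, away from 0
  near_high_u <- c(1 - eps, 1, 1, 1, 1, 1)
  g2 <- thetafit:::barrier_grad(near_high_u, 1)
  expect_gt(g2[1], 0) # U_inc pushed back below 1
})

test_that("adjoint gradients of the full loss match finite differences", {
  cfg <- two_pop_network()
  # the coarse grid has strong curvature along the drive pathway, so the
  # central-difference step must be small to stay in the linear regime
  gc1 <- gradient_check(cfg, duration_ms = 60, epsilon = 1e-6,
                        N = 200, dt = 0.2)
  expect_lt(gc1$max_rel_error, 1e-3)
})

test_that("a synapse from a silent source has (near) zero gradient", {
  p1 <- population_spec("p1", I_ext = 1.1,
                        target = theta_profile_params(20, 0.3, 7, 1.0))
  silent <- population_spec("silent", role = "external_input",
                            target = theta_profile_params(0, 0, 7, 0))
  cn <- connection_spec("silent", "p1", E_syn = 0, g_syn_max = 0.3, w = 20)
  cfg <- network_config(list(p1, silent), list(cn))
  gc1 <- gradient_check(cfg, duration_ms = 60,
                        parameters = "silent.p1.g_syn_max",
                        N = 200, dt = 0.2)
  # only the barrier contributes, identically in both routes
  bg <- thetafit:::barrier_grad(flatten_parameters(cfg), 1)[6]
  expect_equal(gc1$table$adjoint, bg, tolerance = 1e-10)
  expect_equal(gc1$table$finite_diff, bg, tolerance = 1e-6)
})

test_that("zero iterations echo the initial parameters", {
  cfg <- toy_network()
  fit <- fit_network(cfg, n_iterations = 0, dt = 0.2, N = 200)
  expect_equal(fit$parameters, flatten_parameters(cfg))
  expect_length(fit$loss_history, 0)
  fit2 <- ablation_no_stp(cfg, n_iterations = 0, dt = 0.2, N = 200)
  expect_equal(fit2$parameters, flatten_parameters(cfg))
  expect_true(fit2$no_stp)
})

test_that("fitting is deterministic: identical runs, identical histories", {
  cfg <- toy_network()
  f1 <- fit_network(cfg, n_iterations = 5, dt = 0.2, N = 200)
  f2 <- fit_network(cfg, n_iterations = 5, dt = 0.2, N = 200)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$parameters, f2$parameters)
})

test_that("short Adam descent reduces the loss from a perturbed start", {
  cfg <- toy_network(g_syn_max = 0.45, U_inc = 0.375) # misfit start
  truth <- toy_network()
  cyc <- cycle_ms(7)
  run <- run_cbrd(truth, 4 * cyc, dt = 0.2, N = 200)
  win <- run$times > 2 * cyc
  tgt <- list(p1 = rate_trace(run$times[win], pmax(run$rates[win, 1], 0),
                              "p1", 7))
  fit <- fit_network(cfg, targets = tgt, n_iterations = 60, dt = 0.2,
                     N = 200)
  expect_lt(fit$sim_loss_history[60], 0.7 * fit$sim_loss_history[1])
})

test_that("frozen-plasticity fits report their ablated dynamics", {
  cfg <- toy_network()
  ev_stp <- evaluate_loss(cfg, dt = 0.2, N = 200)
  ev_no <- evaluate_loss(cfg, dt = 0.2, N = 200, no_stp = TRUE)
  # removing depression leaves more resources: the driven population fires
  # at least as much without STP
  expect_gte(mean(ev_no$rates), mean(ev_stp$rates))
  expect_false(isTRUE(all.equal(ev_no$L_sim, ev_stp$L_sim)))
})

test_that("parameters save and load through JSON losslessly", {
  cfg <- two_pop_network()
  th <- flatten_parameters(cfg)
  f <- tempfile(fileext = ".json")
  save_parameters(th, f)
  th2 <- load_parameters(f)
  expect_equal(th2, th)
  unlink(f)
})
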