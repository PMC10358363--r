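test_that("the shipped default network has the reference topology", {
  cfg <- default_network()
  expect_s3_class(cfg, "network_config")
  expect_length(cfg$populations, 10)
  expect_equal(cfg$K, 7)
  expect_equal(cfg$M, 49)
  expect_setequal(simulated_populations(cfg),
                  c("pvbas", "olm", "cckbas", "ivy", "ngf", "bis", "aac"))
  expect_setequal(external_populations(cfg), c("ca3pyr", "ca1pyr", "ec3"))
})

test_that("connectivity polarity follows source identity", {
  conns <- default_connectivity()
  expect_length(conns, 49)
  ext <- c("ca3pyr", "ca1pyr", "ec3")
  for (cn in conns) {
    if (cn$pre %in% ext) {
      expect_equal(cn$E_syn, 0)
    } else {
      expect_equal(cn$E_syn, -75)
    }
  }
  keys <- vapply(conns, function(cn) paste(cn$pre, cn$post), "")
  expect_false(anyDuplicated(keys) > 0)
  posts <- vapply(conns, `[[`, "", "post")
  expect_false(any(posts %in% ext))
})

test_that("trainable parameter inventory is 6M + K", {
  expect_equal(count_trainable_parameters(default_network()), 301L)
  one <- network_config(list(population_spec("a")))
  expect_equal(count_trainable_parameters(one), 1L)
  p <- list(population_spec("a"), population_spec("b"))
  cns <- list(connection_spec("a", "b", E_syn = -75),
              connection_spec("b", "a", E_syn = -75),
              connection_spec("a", "a", E_syn = -75))
  expect_equal(count_trainable_parameters(network_config(p, cns)), 20L)
})

test_that("config validation names the offending record", {
  expect_error(connection_spec("a", "b", E_syn = 0, U_inc = 1.2),
               "connection a->b.*U_inc")
  expect_error(connection_spec("a", "b", E_syn = 0, tau_d = 0),
               "tau_f, tau_r, tau_d")
  expect_error(population_spec("bad", V_reset = -40), "V_reset")
  p <- list(population_spec("a"),
            population_spec("x", role = "external_input",
                            target = theta_profile_params(1, 0.3)))
  expect_error(
    network_config(p, list(connection_spec("a", "missing", E_syn = -75))),
    "unresolved.*missing")
  expect_error(
    network_config(p, list(connection_spec("a", "x", E_syn = -75))),
    "external_input")
  expect_error(
    network_config(p, list(connection_spec("a", "a", E_syn = -75),
                           connection_spec("a", "a", E_syn = -75))),
    "duplicate")
})

test_that("save/load round-trips a configuration exactly", {
  cfg <- default_network()
  f <- tempfile(fileext = ".yaml")
  save_config(cfg, f)
  cfg2 <- load_config(f)
  expect_equal(cfg2$M, cfg$M)
  expect_equal(cfg2$K, cfg$K)
  expect_equal(flatten_parameters(cfg2), flatten_parameters(cfg))
  for (nm in names(cfg$populations)) {
    a <- cfg$populations[[nm]]
    b <- cfg2$populations[[nm]]
    for (f2 in c("role", "C_m", "g_L", "E_L", "V_T", "V_reset", "sigma_m",
                 "refractory", "I_ext")) {
      expect_identical(a[[f2]], b[[f2]], label = sprintf("%s$%s", nm, f2))
    }
    if (!is.null(a$target)) {
      expect_equal(unclass(a$target), unclass(b$target))
    }
  }
  unlink(f)
  # minimal config: one population, zero connections
  one <- network_config(list(population_spec("solo")))
  f2 <- tempfile(fileext = ".yaml")
  save_config(one, f2)
  expect_equal(load_config(f2)$K, 1)
  unlink(f2)
  expect_error(load_config("no/such/file.yaml"), "not found")
})

test_that("parameter flattening and application are inverse", {
  cfg <- two_pop_network()
  theta <- flatten_parameters(cfg)
  expect_length(theta, 6 * cfg$M + cfg$K)
  theta2 <- theta * 1.1
  cfg2 <- apply_parameters(cfg, theta2)
  expect_equal(unname(flatten_parameters(cfg2)), unname(theta2))
})
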