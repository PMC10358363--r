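test_that("kappa_from_R matches direct arithmetic on each branch", {
  # branch values computed independently from the piecewise definition
  expect_equal(kappa_from_R(0), 0)
  expect_equal(kappa_from_R(0.3), 2 * 0.3 + 0.3^3 + 5 / 6 * 0.3^5,
               tolerance = 1e-12)
  expect_equal(kappa_from_R(0.6), -0.4 + 1.39 * 0.6 + 0.43 / 0.4,
               tolerance = 1e-12)
  expect_equal(kappa_from_R(0.9), 1 / (3 * 0.9 - 4 * 0.81 + 0.729),
               tolerance = 1e-12)
  expect_error(kappa_from_R(1), "\\[0, 1\\)")
  expect_error(kappa_from_R(-0.1), "\\[0, 1\\)")
})

test_that("kappa_from_R is nondecreasing with small branch-boundary jumps", {
  R <- seq(0, 0.99, by = 0.001)
  k <- kappa_from_R(R)
  expect_true(all(diff(k) > -1e-12))
  for (b in c(0.53, 0.85)) {
    lo <- kappa_from_R(b - 1e-9)
    hi <- kappa_from_R(b + 1e-9)
    expect_lt(abs(hi - lo), 0.05)
  }
})

test_that("rate profiles average to FR_mean and peak at exp(kappa)/I0", {
  times <- seq(0.1, cycle_ms(7), by = 0.1)
  # unmodulated profile is constant
  flat <- rate_profile(theta_profile_params(10, 0, 7, 0), times)
  expect_equal(flat$rates, rep(10, length(times)), tolerance = 1e-12)
  # one cycle of the pvbas profile averages to its mean rate
  pv <- rate_profile(target_registry("pvbas"), times)
  expect_equal(mean(pv$rates), 24, tolerance = 1e-3)
  # peak value FR_mean e^kappa / I0(kappa), with kappa from an independent
  # Bessel-function evaluation
  kappa <- kappa_from_R(0.3)
  expect_equal(max(pv$rates), 24 * exp(kappa) / besselI(kappa, 0),
               tolerance = 1e-4)
})

test_that("profile registry holds the ten reference populations", {
  reg <- target_registry()
  expect_length(reg, 10)
  ec3 <- target_registry("ec3")
  expect_equal(ec3$R, 0.2)
  expect_equal(ec3$omega_theta, 7)
  expect_equal(ec3$FR_mean, 1.5)
  expect_equal(ec3$phi, -1.57)
  ngf <- target_registry("ngf")
  expect_equal(ngf$FR_mean, 8)
  expect_equal(ngf$phi, 0)
  expect_error(target_registry("nonexistent"), "unknown population")
})

test_that("circular statistics of generated profiles recover the registry rows", {
  times <- seq(0.1, 2 * cycle_ms(7), by = 0.1)
  for (nm in names(target_registry())) {
    pr <- target_registry(nm)
    cs <- circular_stats(rate_profile(pr, times, population = nm))
    expect_equal(cs$mean_rate, pr$FR_mean, tolerance = 1e-3,
                 label = sprintf("%s mean rate", nm))
    if (pr$R > 0) {
      # the 7 Hz cycle is incommensurate with the 0.1 ms grid, so the
      # analysis window misses an exact integer cycle count by < one step
      expect_equal(cs$mean_phase, pr$phi, tolerance = 1e-3,
                   label = sprintf("%s mean phase", nm))
    }
    expect_lt(abs(cs$R - pr$R), 0.01)
  }
})

test_that("poisson generation is exact, reproducible and unbiased", {
  times <- seq(0.1, 1000, by = 0.1)
  zero <- rate_trace(times, rep(0, length(times)))
  expect_identical(poisson_spikes(zero, 3, seed = 1),
                   replicate(3, numeric(0), simplify = FALSE))
  const <- rate_trace(times, rep(10, length(times)))
  sp1 <- poisson_spikes(const, 200, seed = 42)
  sp2 <- poisson_spikes(const, 200, seed = 42)
  expect_identical(sp1, sp2)
  total <- sum(lengths(sp1))
  expected <- 10 * 200 * 1 # 10 spikes/s x 200 generators x 1 s
  expect_lt(abs(total - expected), 4 * sqrt(expected))
  # inhomogeneous: realized spike-phase distribution follows the profile
  pv <- rate_profile(target_registry("pvbas"), seq(0.1, 2000, by = 0.1))
  sp <- poisson_spikes(pv, 100, seed = 7)
  ph <- theta_phase(unlist(sp), 7)
  mp <- Arg(sum(exp(1i * ph)))
  expect_lt(abs(mp - 1.57), 0.15)
})

test_that("rate traces validate inputs and round-trip through CSV", {
  expect_error(rate_trace(c(1, 2), c(-1, 0)), "nonnegative")
  expect_error(rate_trace(c(2, 1), c(1, 1)), "increasing")
  tr <- rate_profile(target_registry("olm"), seq(0.1, 100, by = 0.1), "olm")
  f <- tempfile(fileext = ".csv")
  write_rate_trace(tr, f)
  df <- read.csv(f)
  expect_equal(df$rate_spikes_per_s, tr$rates)
  expect_equal(unique(df$population), "olm")
  unlink(f)
})
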