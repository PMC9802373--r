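test_that("trace model enforces the harmonic friction relation", {
  m <- trace_model(mean = 800, variance = 150, tau_c = 0.01)
  expect_equal(m$gamma, m$kBT * m$tau_c / m$variance)
  expect_error(trace_model(800, -1, 0.01), "positive")
  expect_error(trace_model(800, 100, 0.01, rate = 10, duration = 1),
               "1000 samples")
})

test_that("OU generator reproduces the stationary statistics", {
  m <- trace_model(mean = 800, variance = 150, tau_c = 0.01,
                   rate = 1000, duration = 1000)
  tr <- generate_ou_trace(m, seed = 7)
  n <- length(tr$z)
  expect_equal(n, 1e6)
  # variance within 3 SE (SE inflated by correlation: neff = n dt / 2 tau_c)
  neff <- n / (2 * m$tau_c * m$rate)
  se_var <- m$variance * sqrt(2 / neff)
  expect_lt(abs(var(tr$z) - m$variance), 3 * se_var)
  expect_lt(abs(mean(tr$z) - 800), 3 * sqrt(m$variance * 2 * m$tau_c *
                                              m$rate / n) * 3)
  # lag-1 autocorrelation = exp(-dt/tau_c)
  r1 <- cor(tr$z[-1], tr$z[-n])
  expect_equal(r1, exp(-1e-3 / 0.01), tolerance = 0.01)
  # determinism
  tr2 <- generate_ou_trace(m, seed = 7)
  expect_identical(tr$z, tr2$z)
})

test_that("vanishing correlation time gives white noise", {
  m <- trace_model(mean = 0, variance = 25, tau_c = 1e-9,
                   rate = 1000, duration = 1000)
  tr <- generate_ou_trace(m, seed = 3)
  n <- length(tr$z)
  expect_lt(abs(cor(tr$z[-1], tr$z[-n])), 0.01)
})

test_that("switching generator reproduces dwell times and occupancies", {
  sw <- switching_model(ddlk = -1:1, occupancy = c(0.25, 0.5, 0.25),
                        tau_p = 2, spacing = 48, base_extension = 500)
  base <- trace_model(mean = 500, variance = 9, tau_c = 0.005,
                      rate = 200, duration = 4000)
  tr <- generate_switching_trace(sw, base, seed = 11)
  st <- tr$state
  # occupancies within a multinomial-style tolerance
  occ <- tabulate(st, 3) / length(st)
  expect_lt(max(abs(occ - sw$levels$p)), 0.05)
  # observed dwell in state i is exponential with mean tau_p / (1 - p_i)
  r <- rle(st)
  for (i in 1:3) {
    d <- r$lengths[r$values == i][-1] / base$rate  # drop first (censored-ish)
    d <- d[-length(d)]
    expect_gt(length(d), 200)
    tau_hat <- mean(d)
    tau_true <- sw$levels$tau_dwell[i]
    expect_lt(abs(tau_hat - tau_true), 3 * tau_true / sqrt(length(d)))
  }
  # single level reduces to a pure OU trace
  sw1 <- switching_model(ddlk = 0, occupancy = 1, tau_p = 2,
                         base_extension = 500)
  tr1 <- generate_switching_trace(sw1, base, seed = 11)
  expect_true(all(tr1$state == 1))
  expect_lt(abs(var(tr1$z) - base$variance), 1.5)
})

test_that("rotation dataset: zero noise reproduces theory; sigma_p recovery
          under noise", {
  mol <- molecule_spec(7900)
  sig <- seq(0.025, 0.055, length.out = 8)
  exact <- generate_rotation_dataset(0.5, sig, mol, rel_noise = 0, seed = 1)[[1]]
  th <- theory_rotation_curve(sig, 0.5, mol)
  expect_equal(exact$z, th$z, tolerance = 1e-12)
  expect_equal(exact$var_z, th$var_z, tolerance = 1e-12)
  # noiseless linear extrapolation recovers sigma_p exactly
  cal0 <- suppressWarnings(calibrate_fluctuations(exact, n_boot = 0))
  cx <- solve_coexistence(0.5, default_params)
  expect_equal(cal0$sigma_p, cx$sigma_p, tolerance = 1e-6)
  # with 2% noise, sigma_p recovered within 3% over 100 seeds
  errs <- sapply(1:100, function(s) {
    cv <- generate_rotation_dataset(0.5, sig, mol, rel_noise = 0.02,
                                    seed = s)[[1]]
    cal <- suppressWarnings(calibrate_fluctuations(cv, n_boot = 0))
    abs(cal$sigma_p - cx$sigma_p) / cx$sigma_p
  })
  expect_lt(mean(errs < 0.03), 1.01)
  expect_gt(mean(errs < 0.03), 0.9)
})
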