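p <- default_params

test_that("windowed statistics: constant, i.i.d. and correlated traces", {
  tr_const <- extension_trace(time = (0:9999) / 1000, z = rep(5, 10000),
                              rate = 1000)
  ws <- windowed_stats(tr_const, 1)
  expect_equal(ws$var, 0)
  expect_equal(ws$mean, 5)

  set.seed(42)
  tr_iid <- extension_trace(time = (0:99999) / 1000,
                            z = rnorm(1e5, 0, 3), rate = 1000)
  ws2 <- windowed_stats(tr_iid, 1)
  # pooled variance ~ chi-square: SE = s^2 sqrt(2/(w-1)) / sqrt(k)
  se <- 9 * sqrt(2 / 999) / sqrt(100)
  expect_lt(abs(ws2$var - 9), 3 * se)

  # OU trace with tau_c = 10 ms, 1 s windows: pooled variance within 5%
  m <- trace_model(mean = 0, variance = 100, tau_c = 0.01, rate = 1000,
                   duration = 200)
  ws3 <- windowed_stats(generate_ou_trace(m, seed = 5), 1)
  expect_lt(abs(ws3$var - 100) / 100, 0.05)

  expect_error(windowed_stats(tr_const, 0.005), "10 samples")
})

test_that("autocorrelation time recovers the OU correlation time", {
  m <- trace_model(mean = 0, variance = 50, tau_c = 0.005, rate = 1000,
                   duration = 400)
  act <- autocorrelation_time(generate_ou_trace(m, seed = 8))
  expect_lt(abs(act$tau_c - 0.005) / 0.005, 0.10)
  expect_true(act$decaying)

  # white noise: tau_c below one sample interval
  mw <- trace_model(mean = 0, variance = 50, tau_c = 1e-9, rate = 1000,
                    duration = 100)
  actw <- autocorrelation_time(generate_ou_trace(mw, seed = 2))
  expect_lte(actw$tau_c, 1e-3)

  # harmonic relation: gamma = kBT tau_c / <dz^2> recovered within 15%
  m2 <- trace_model(mean = 0, variance = 120, tau_c = 0.02, rate = 1000,
                    duration = 600)
  tr2 <- generate_ou_trace(m2, seed = 13)
  tau_hat <- autocorrelation_time(tr2)$tau_c
  gamma_hat <- m2$kBT * tau_hat / var(tr2$z)
  expect_lt(abs(gamma_hat - m2$gamma) / m2$gamma, 0.15)

  # non-decaying autocorrelation (strong drift) is flagged
  drift <- extension_trace(time = (0:19999) / 1000,
                           z = seq(0, 100, length.out = 20000), rate = 1000)
  expect_warning(autocorrelation_time(drift), "decay")
})

test_that("rotation-curve fits recover exact branches and buckling", {
  mol <- molecule_spec(7900, p)
  cx <- solve_coexistence(0.5, p)
  sig <- c(seq(0.001, cx$sigma_s * 0.95, length.out = 5),
           seq(cx$sigma_s * 1.3, cx$sigma_p * 0.95, length.out = 6))
  cv <- theory_rotation_curve(sig, 0.5, mol)
  fit <- fit_rotation_curve(cv)
  # postbuckling slope equals -Gamma L (slope vs sigma), i.e. Gamma L / Lk0
  # per turn, to high precision
  expect_equal(fit$post$slope, -cx$Gamma * mol$L, tolerance = 1e-6)
  expect_equal(fit$post$slope_per_turn, cx$Gamma * mol$L / mol$Lk0,
               tolerance = 1e-6)
  expect_equal(fit$sigma_buckling, cx$sigma_s, tolerance = 0.1)

  # curvature of a pure quadratic recovered exactly
  cvq <- cv
  cvq$z <- 1000 - 5e4 * cvq$sigma^2
  fitq <- fit_rotation_curve(cvq)
  expect_equal(fitq$pre$curvature, -5e4, tolerance = 1e-6)

  # with bead-tracking-scale noise (0.2% of the micron-scale extension),
  # the buckling density is recovered within 5% of sigma_s
  errs <- sapply(1:60, function(s) {
    cvn <- generate_rotation_dataset(0.5, sig, mol, rel_noise = 0.002,
                                     seed = 1000 + s)[[1]]
    abs(fit_rotation_curve(cvn)$sigma_buckling - cx$sigma_s) / cx$sigma_s
  })
  expect_gt(mean(errs < 0.05), 0.85)
})

test_that("calibration matches the theory oracle and the kappa limit", {
  mol <- molecule_spec(7900, p)
  cx <- solve_coexistence(0.5, p)
  sig <- seq(cx$sigma_s * 1.3, cx$sigma_p * 0.9, length.out = 7)
  cal <- suppressWarnings(
    calibrate_fluctuations(theory_rotation_curve(sig, 0.5, mol), n_boot = 0))
  expect_equal(cal$sigma_p, cx$sigma_p, tolerance = 1e-4)
  # kappa from extrapolation equals the sigma -> sigma_p variance limit
  expect_equal(cal$kappa, cx$kappa, tolerance = 1e-3)
  expect_equal(cal$kappa,
               extension_variance(cx$sigma_p * 0.9999, 0.5, p),
               tolerance = 1e-3)
  expect_error(calibrate_fluctuations(
    theory_rotation_curve(sig[1:3], 0.5, mol)), "4 postbuckling")
})

test_that("domain-size inference inverts the forward variance drop", {
  mol <- molecule_spec(7900, p)
  cx <- solve_coexistence(0.5, p)
  sig <- seq(cx$sigma_s * 1.3, cx$sigma_p * 0.9, length.out = 7)
  cal <- suppressWarnings(
    calibrate_fluctuations(theory_rotation_curve(sig, 0.5, mol), n_boot = 0))
  v0 <- 8000
  for (dl in c(0, 113, 254, 912)) {
    out <- infer_domain_size(v0, v0 - cal$kappa * dl, cal)
    expect_equal(out$delta_L, dl, tolerance = 1e-9)
    expect_equal(out$diagnostic, "ok")
  }
  # property: inversion is exact for any kappa > 0 and delta_L >= 0
  set.seed(1)
  for (rep in 1:20) {
    kap <- runif(1, 0.5, 20)
    dl <- runif(1, 0, 0.9 * v0 / kap)
    calx <- cal
    calx$kappa <- kap
    calx$kappa_se <- 0
    expect_equal(infer_domain_size(v0, v0 - kap * dl, calx)$delta_L, dl,
                 tolerance = 1e-9)
  }
  # a variance increase is a diagnostic, not an error
  out2 <- infer_domain_size(1000, 1100, cal)
  expect_equal(out2$delta_L, 0)
  expect_equal(out2$diagnostic, "no_bridging")
})

test_that("mean-extension change: identity, construction and mismatch", {
  m <- trace_model(mean = 700, variance = 100, tau_c = 0.005, rate = 1000,
                   duration = 60)
  tr <- generate_ou_trace(m, seed = 21, force = 0.5, sigma = 0.04)
  expect_equal(mean_extension_change(tr, tr)$delta_z, 0)
  shifted <- tr
  shifted$z <- tr$z + 10
  ch <- mean_extension_change(tr, shifted)
  expect_equal(ch$delta_z, 10, tolerance = 1e-9)
  other <- generate_ou_trace(m, seed = 22, force = 1.0, sigma = 0.04)
  expect_error(mean_extension_change(tr, other), "different force")
})

test_that("state segmentation: single level, three levels, square wave", {
  # single-level OU trace: one state
  m1 <- trace_model(mean = 640, variance = 100, tau_c = 0.01, rate = 100,
                    duration = 2000)
  sm1 <- segment_states(generate_ou_trace(m1, seed = 31))
  expect_equal(nrow(sm1$levels), 1)

  # three-level switching trace, spacing 48 nm, tau_p = 65 s
  sw <- switching_model(ddlk = -1:1, occupancy = c(0.2, 0.6, 0.2),
                        tau_p = 65, spacing = 48, base_extension = 800)
  base <- trace_model(mean = 800, variance = 120, tau_c = 0.01, rate = 100,
                      duration = 20000)
  tr <- generate_switching_trace(sw, base, seed = 17)
  sm <- segment_states(tr, filter_window_s = 10)
  expect_equal(nrow(sm$levels), 3)
  expect_lt(abs(sm$spacing - 48), 2)
  # >= 95% of assignable samples match the ground truth
  idx <- !is.na(sm$assignments)
  lv_order <- order(sm$levels$z, decreasing = TRUE)  # z descending = ddlk -1,0,1
  truth_z <- sw$levels$z[tr$state]
  assigned_z <- sm$levels$z[sm$assignments[idx]]
  match_frac <- mean(abs(assigned_z - truth_z[idx]) < 24)
  expect_gt(match_frac, 0.95)

  # two equally occupied levels: occupancies 0.5/0.5
  n <- 4e5
  square <- rep(rep(c(0, 48), each = 4000), length.out = n) +
    rnorm(n, 0, 3)
  trs <- extension_trace(time = (seq_len(n) - 1) / 100, z = square,
                         rate = 100)
  sms <- segment_states(trs, filter_window_s = 10)
  expect_equal(nrow(sms$levels), 2)
  expect_lt(max(abs(sms$levels$p - 0.5)), 0.05)
})

test_that("plectoneme stiffness from occupancies: exact inversion and
          linearity in delta_L", {
  # Gaussian occupancies of width delta_L / (4 pi^2 * 20 nm) must return
  # P = 20 nm exactly
  dl <- 254
  v <- dl / (4 * pi^2 * 20)
  k <- -2:2
  occ <- exp(-k^2 / (2 * v))
  sm <- list(levels = data.frame(ddlk = k, p = occ / sum(occ)))
  est <- plectoneme_stiffness(sm, delta_L = dl)
  expect_equal(est$P, 20, tolerance = 1e-9)
  expect_equal(est$ddlk_var, v, tolerance = 1e-9)
  # doubling delta_L at fixed width doubles P
  est2 <- plectoneme_stiffness(sm, delta_L = 2 * dl)
  expect_equal(est2$P, 40, tolerance = 1e-9)
  # anti-Gaussian (convex, edge-favoring) occupancies are flagged
  smx <- list(levels = data.frame(ddlk = k, p = c(.3, .15, .1, .15, .3)))
  expect_error(plectoneme_stiffness(smx, dl), "Gaussian")
})

test_that("dwell-time analysis: exponential MLE identities", {
  # tau_i = tau_p / (1 - p_i): two states at p = 0.5 give tau_i = 2 tau_p
  sw <- switching_model(ddlk = c(0, 1), occupancy = c(0.5, 0.5), tau_p = 10,
                        spacing = 60, base_extension = 500)
  expect_equal(sw$levels$tau_dwell, c(20, 20))

  # ML mean of an exponential equals the arithmetic mean (after the
  # truncation shift)
  set.seed(9)
  d <- rexp(500, 1 / 30) + 10
  sm <- list(levels = data.frame(ddlk = 0, z = 0, p = 0.4, n_samples = 1),
             assignments = NULL, filter_window_s = 10, rate = 1)
  # construct assignments encoding these dwells in state 1 alternating with
  # a dummy state 2
  lens <- as.integer(round(as.vector(rbind(d, 15))))
  sm$assignments <- rep(rep(c(1L, 2L), 500), times = lens)
  sm$levels <- data.frame(ddlk = c(0, 1), z = c(0, 60), p = c(0.4, 0.6),
                          n_samples = c(1, 1))
  dw <- suppressWarnings(dwell_time_analysis(sm, min_events = 20))
  tau_hat <- dw$per_state$tau_dwell[1]
  expect_equal(tau_hat, mean(round(d)[-c(1)][-499]) - 10, tolerance = 0.2)
  expect_equal(dw$per_state$tau_p[1], (1 - 0.4) * tau_hat, tolerance = 1e-9)
})
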