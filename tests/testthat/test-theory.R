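p <- default_params

test_that("free energies are even in sigma and have the quadratic structure", {
  for (f in c(0.3, 0.5, 2)) {
    for (s in c(0.01, 0.025, 0.05)) {
      expect_equal(stretched_free_energy(s, f, p),
                   stretched_free_energy(-s, f, p))
      expect_gt(stretched_free_energy(s, f, p),
                stretched_free_energy(s / 2, f, p))
    }
  }
  expect_equal(plectoneme_free_energy(0, p), 0)
  # quadratic form: P(sigma)/P(2 sigma) = 1/4
  expect_equal(plectoneme_free_energy(0.02, p) /
                 plectoneme_free_energy(0.04, p), 0.25)
  # hand-evaluated scalar: 1/2 kBT P w0^2 sigma^2
  pp <- elastic_params(P = 20)
  expect_equal(plectoneme_free_energy(0.04, pp),
               0.5 * pp$kBT * 20 * (2 * pi / (10.5 * 0.34))^2 * 0.04^2)
  expect_error(stretched_free_energy(0.01, -1, p), "positive")
})

test_that("relaxed-DNA extension reproduces the stretched worm-like chain", {
  for (f in c(2, 5, 20)) {
    # -dS/df at sigma = 0 equals the high-force WLC fractional extension
    h <- 1e-4 * f
    num <- -(stretched_free_energy(0, f + h, p) -
               stretched_free_energy(0, f - h, p)) / (2 * h)
    expect_equal(num, 1 - 0.5 * sqrt(p$kBT / (p$A * f)), tolerance = 1e-6)
    expect_equal(mean_extension(0, f, p),
                 1 - 0.5 * sqrt(p$kBT / (p$A * f)), tolerance = 1e-10)
  }
})

test_that("double-tangent construction satisfies its defining equations", {
  for (f in c(0.3, 0.5, 1, 2, 4)) {
    cx <- solve_coexistence(f, p)
    expect_lt(cx$sigma_s, cx$sigma_p)
    expect_gt(cx$sigma_s, 0)
    h <- 1e-7
    Sp <- (stretched_free_energy(cx$sigma_s + h, f, p) -
             stretched_free_energy(cx$sigma_s - h, f, p)) / (2 * h)
    Pp <- (plectoneme_free_energy(cx$sigma_p + h, p) -
             plectoneme_free_energy(cx$sigma_p - h, p)) / (2 * h)
    chord <- (plectoneme_free_energy(cx$sigma_p, p) -
                stretched_free_energy(cx$sigma_s, f, p)) /
      (cx$sigma_p - cx$sigma_s)
    expect_equal(Sp, Pp, tolerance = 1e-5)
    expect_equal(Sp, chord, tolerance = 1e-5)
    expect_gt(cx$Gamma, 0)
    expect_gt(cx$kappa, 0)
  }
  # degenerate tangent reported, not clamped
  expect_error(solve_coexistence(0.03, p), "degenerate")
})

test_that("double-tangent solution matches a brute-force grid minimization", {
  cx <- solve_coexistence(0.5, p)
  gr <- grid_coexistence(0.5, p)
  expect_equal(cx$sigma_s, gr$sigma_s, tolerance = 0.02)
  expect_equal(cx$sigma_p, gr$sigma_p, tolerance = 0.02)
  expect_equal(supercoil_free_energy(0.035, 0.5, p), gr$F, tolerance = 1e-3)
})

test_that("mean extension is continuous at buckling and linear beyond", {
  for (f in c(0.5, 1, 2)) {
    cx <- solve_coexistence(f, p)
    lo <- mean_extension(cx$sigma_s * (1 - 1e-9), f, p)
    hi <- mean_extension(cx$sigma_s * (1 + 1e-9), f, p)
    expect_equal(lo, hi, tolerance = 1e-6)
    # exactly linear on the coexistence branch, vanishing at sigma_p
    s <- seq(cx$sigma_s * 1.05, cx$sigma_p * 0.999, length.out = 9)
    z <- mean_extension(s, f, p)
    expect_equal(max(abs(resid(lm(z ~ s)))), 0, tolerance = 1e-12)
    expect_equal(mean_extension(cx$sigma_p, f, p), 0, tolerance = 1e-9)
  }
  expect_error(mean_extension(-0.01, 0.5, p), "underwound")
  expect_error(mean_extension(0.2, 0.5, p), "plectonemic")
})

test_that("fluctuation-response: variance equals kBT d<z>/df and matches the
          free-energy curvature oracle", {
  for (f in c(0.5, 1, 2)) {
    cx <- solve_coexistence(f, p)
    for (s in c(0.3 * cx$sigma_s, 0.8 * cx$sigma_s,
                0.5 * (cx$sigma_s + cx$sigma_p), 0.95 * cx$sigma_p)) {
      v <- extension_variance(s, f, p)
      h <- 1e-3 * f
      d2F <- (supercoil_free_energy(s, f + h, p) -
                2 * supercoil_free_energy(s, f, p) +
                supercoil_free_energy(s, f - h, p)) / h^2
      expect_equal(v, -p$kBT * d2F, tolerance = 1e-4)
      expect_gt(v, 0)
    }
    # variance approaches kappa at the plectonemic boundary
    expect_equal(extension_variance(cx$sigma_p * 0.9999, f, p), cx$kappa,
                 tolerance = 2e-3)
    # monotone non-decreasing in sigma over [0, sigma_p]
    grid <- seq(0, cx$sigma_p * 0.999, length.out = 25)
    expect_true(all(diff(extension_variance(grid, f, p)) > -1e-9))
  }
})

test_that("coexistence free energy is linear in sigma", {
  cx <- solve_coexistence(1, p)
  s <- seq(cx$sigma_s * 1.02, cx$sigma_p * 0.98, length.out = 11)
  F <- supercoil_free_energy(s, 1, p)
  expect_lt(max(abs(diff(diff(F)))), 1e-10)
})

test_that("scaling exponents: exact power law and the four model exponents", {
  f <- c(1, 2, 4, 8, 16)
  expect_equal(fit_scaling_exponent(f, 3 * f^(-1.5)), -1.5,
               tolerance = 1e-12)
  expect_error(fit_scaling_exponent(c(1, 2, -3, 4), rep(1, 4)), "positive")
  expect_error(fit_scaling_exponent(c(1, 2, 3), rep(1, 3)), "at least 4")

  # prebuckling curvature of <z> vs sigma over 10..100 pN scales ~ f^{-3/2}
  fpre <- exp(seq(log(10), log(100), length.out = 6))
  curv_z <- sapply(fpre, function(f) {
    s <- 0.002
    (mean_extension(s, f, p) - mean_extension(0, f, p)) / s^2
  })
  expect_equal(fit_scaling_exponent(fpre, curv_z), -1.5, tolerance = 0.1)

  # postbuckling slope of <z> vs sigma over 0.5..4 pN scales ~ f^{-1/2}
  fpost <- exp(seq(log(0.5), log(4), length.out = 6))
  slope_z <- sapply(fpost, function(f) -solve_coexistence(f, p)$Gamma)
  expect_equal(fit_scaling_exponent(fpost, slope_z), -0.5, tolerance = 0.15)
})
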