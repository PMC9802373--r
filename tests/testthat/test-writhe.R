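test_that("planar conformations have zero writhe and mirrors negate it", {
  th <- seq(0, pi, length.out = 60)
  arc <- cbind(20 * sin(th), 0, 40 * th)
  expect_equal(writhe(arc), 0, tolerance = 1e-12)
  hel <- cbind(8 * cos(seq(0, 6 * pi, length.out = 120)),
               8 * sin(seq(0, 6 * pi, length.out = 120)),
               seq(0, 100, length.out = 120))
  w <- writhe(hel)
  mir <- hel
  mir[, 2] <- -mir[, 2]
  expect_equal(writhe(mir), -w, tolerance = 1e-12)
  expect_gt(abs(w), 1)
})

test_that("pairwise closed form matches fine-grid Gauss quadrature", {
  # the exact pairwise sum on a coarse polygon and midpoint quadrature on a
  # much finer polygon both converge to the smooth-curve writhe
  w_exact <- writhe(torus_curve(400), closed = TRUE)
  w_quad <- writhe_quadrature(torus_curve(1500))
  expect_equal(w_exact, w_quad, tolerance = 1e-3)
})

test_that("solenoid writhe matches the helix closed form", {
  # n turns of radius r and pitch h per turn: Wr ~ n (1 - h/ell)
  n <- 5; r <- 10; h <- 25
  ell <- sqrt((2 * pi * r)^2 + h^2)
  t <- seq(0, 2 * pi * n, length.out = 400)
  hel <- cbind(r * cos(t), r * sin(t), h * t / (2 * pi))
  # extend straight ends so the open-chain closure is clean
  hel <- rbind(c(r, 0, -8 * r), hel, c(r * cos(2 * pi * n),
                                       r * sin(2 * pi * n), h * n + 8 * r))
  expect_equal(writhe(hel), n * (1 - h / ell), tolerance = 0.05)
})

test_that("degenerate inputs are rejected", {
  expect_error(writhe(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))),
               "coincident")
  expect_error(writhe(rbind(c(0, 0, 0), c(1, 0, 0))), "at least 3")
})
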