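p <- default_params

test_that("chain constructors satisfy the conformational invariants", {
  for (init in c("straight", "solenoid", "plectoneme")) {
    ch <- dna_chain(1500, delta_lk = 6, a = 2.5, init = init, force = 0.5)
    seglen <- sqrt(rowSums(diff(ch$positions)^2))
    expect_lt(max(abs(seglen - ch$a)), 1e-9 * ch$a)
    expect_true(validate_chain(ch))
  }
  # solenoid and plectoneme starts pre-store writhe of the right sign
  expect_gt(writhe(dna_chain(1500, 6, init = "solenoid")), 1)
  expect_lt(writhe(dna_chain(1500, -6, init = "solenoid")), -1)
})

test_that("bending and twist energies match their scalar formulas", {
  # straight chain: zero bending
  ch <- quick_chain(400, a = 2.5)
  ch$positions <- cbind(0, 0, (seq_len(nrow(ch$positions)) - 1) * 2.5)
  expect_equal(bending_energy(ch), 0, tolerance = 1e-20)
  # single joint at theta: (A/a)(1 - cos theta)
  th <- 0.4
  pos <- rbind(c(0, 0, 0), c(0, 0, 2.5),
               c(2.5 * sin(th), 0, 2.5 + 2.5 * cos(th)))
  ch3 <- list(positions = pos, a = 2.5, params = p, delta_lk = 0,
              L = 5, excluded_diameter = 4)
  class(ch3) <- "dna_chain"
  expect_equal(bending_energy(ch3), (40 / 2.5) * (1 - cos(th)),
               tolerance = 1e-12)
  # random chain: sum equals an independent per-joint accumulation
  ch <- quick_chain(500, delta_lk = 3, init = "solenoid")
  acc <- 0
  posn <- ch$positions
  for (b in 2:(nrow(posn) - 1)) {
    u <- (posn[b, ] - posn[b - 1, ]) / ch$a
    v <- (posn[b + 1, ] - posn[b, ]) / ch$a
    acc <- acc + (p$A / ch$a) * (1 - sum(u * v))
  }
  expect_equal(bending_energy(ch), acc, tolerance = 1e-9)

  # twist energy: zero when Wr = dLk; scalar evaluation; even in (dLk - Wr)
  ch <- quick_chain(2000, delta_lk = 11.4, a = 2.5, init = "straight")
  expect_equal(twist_energy(ch, wr = 11.4), 0)
  expect_equal(twist_energy(ch, wr = 0),
               2 * pi^2 * 100 / ch$L * 11.4^2, tolerance = 1e-9)
  expect_equal(twist_energy(ch, wr = 11.4 + 2), twist_energy(ch, wr = 11.4 - 2))
})

test_that("MC trajectories conserve linking number, self-avoidance and are
          seed-deterministic", {
  ch <- quick_chain(800, delta_lk = 4, init = "solenoid")
  e1 <- suppressWarnings(mc_run(ch, force = 1, n_steps = 3e4, seed = 9,
                                stride = 500))
  e2 <- suppressWarnings(mc_run(ch, force = 1, n_steps = 3e4, seed = 9,
                                stride = 500))
  expect_identical(e1$samples, e2$samples)       # seeded determinism
  expect_identical(e1$chain$positions, e2$chain$positions)
  e3 <- suppressWarnings(mc_run(ch, force = 1, n_steps = 3e4, seed = 10,
                                stride = 500))
  expect_false(identical(e1$samples$z, e3$samples$z))
  # delta_lk is an immutable label of the run
  expect_identical(e1$chain$delta_lk, ch$delta_lk)
  # twist + writhe bookkeeping: recorded writhe matches a fresh computation
  expect_equal(writhe(e1$chain), e1$wr_final, tolerance = 1e-6)
  # post-hoc self-avoidance scan of the final conformation
  expect_true(validate_chain(e1$chain))
  # segment lengths preserved to machine precision by rigid rotations
  seglen <- sqrt(rowSums(diff(e1$chain$positions)^2))
  expect_lt(max(abs(seglen - ch$a)), 1e-9)
})

test_that("equilibrium bend-angle statistics match the discrete WLC", {
  # at zero force/twist, <1 - cos theta> = 1 - (coth k - 1/k), k = A/a
  pp <- elastic_params(C = 0.001)
  ch <- dna_chain(500, 0, params = pp, a = 2.5, init = "straight")
  vals <- c()
  for (s in 1:4) {
    e <- mc_run(ch, force = 1e-6, n_steps = 5e4, equil = 3e4, stride = 2e4,
                seed = s)
    tv <- diff(e$chain$positions) / ch$a
    vals <- c(vals, 1 - rowSums(tv[-nrow(tv), ] * tv[-1, ]))
  }
  k <- pp$A / ch$a
  exact <- 1 - (1 / tanh(k) - 1 / k)
  se <- sd(vals) / sqrt(length(vals) / 4)  # crude: joints are correlated
  expect_lt(abs(mean(vals) - exact), max(3 * se, 0.15 * exact))
})

test_that("relaxed chain under tension reproduces the stretched WLC", {
  ch <- quick_chain(800, delta_lk = 0, a = 2.5, init = "straight")
  e <- suppressWarnings(mc_run(ch, force = 2, n_steps = 1.2e5, equil = 8e4,
                               stride = 300, seed = 4))
  zfrac <- mean(e$samples$z) / ch$L
  se <- block_se(e$samples$z) / ch$L
  pred <- 1 - 0.5 * sqrt(p$kBT / (p$A * 2))
  # 2 SE plus a 1.5% allowance for discretization and the soft clamp
  expect_lt(abs(zfrac - pred), 2 * se + 0.015)
})

test_that("plectoneme detection partitions the contour exactly", {
  ch <- quick_chain(1000, delta_lk = 0, a = 2.5, init = "straight")
  det <- detect_plectoneme(ch)
  expect_equal(det$L_p, 0)
  expect_equal(det$L_s, ch$L)
  ch2 <- dna_chain(2000, 9, a = 2.5, init = "plectoneme", force = 0.5)
  det2 <- detect_plectoneme(ch2)
  expect_equal(det2$L_p + det2$L_s, ch2$L)     # exact partition
  expect_gt(det2$L_p, 100)                     # superhelix is labeled
  # labels flag the interwound region, not the stems
  expect_equal(det2$labels[1:5], rep(0L, 5))
})

test_that("bridge-site selection obeys its predicates", {
  ch <- quick_chain(1000, delta_lk = 0, a = 2.5, init = "straight")
  expect_equal(nrow(select_bridge_sites(ch)), 0)  # no plectoneme, no sites
  ch2 <- dna_chain(2000, 9, a = 2.5, init = "plectoneme", force = 0.5)
  sites <- select_bridge_sites(ch2, threshold = 8)
  expect_gt(nrow(sites), 0)
  pos <- ch2$positions
  for (r in seq_len(nrow(sites))) {
    i <- sites$i[r]; j <- sites$j[r]
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    expect_lt(d, 8)                               # distance predicate
    ti <- (pos[i + 1, ] - pos[i, ]) / ch2$a
    tj <- (pos[j + 1, ] - pos[j, ]) / ch2$a
    expect_lt(sum(ti * tj), -0.5)                 # opposite strands
    expect_equal(sites$delta_L[r], (j - i) * ch2$a)
  }
  # loop sizes span small to near-full plectoneme
  expect_gt(diff(range(sites$delta_L)), 50)
})

test_that("loop linking number follows the uniform twist partition", {
  # planar torsionally relaxed loop: zero
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  loop <- cbind(10 * cos(th), 10 * sin(th), 0)
  expect_equal(writhe(loop, closed = TRUE), 0, tolerance = 1e-10)

  ch <- dna_chain(2000, 9, a = 2.5, init = "plectoneme", force = 0.5)
  sites <- select_bridge_sites(ch)
  br <- sites[which.max(sites$delta_L), ]
  lk_loop <- loop_linking_number(ch, br)
  # complement = total - loop under the same convention, up to the mutual
  # (loop x complement) writhe which the partition assigns to neither part
  wr_tot <- writhe(ch)
  wr_loop <- writhe(ch$positions[br$i:br$j, ], closed = TRUE)
  tw <- ch$delta_lk - wr_tot
  lk_comp <- (wr_tot - wr_loop) + tw * (ch$L - br$delta_L) / ch$L
  expect_equal(lk_loop + lk_comp, ch$delta_lk, tolerance = 1e-9)
  # the loop actually traps supercoiling: a plectonemic loop carries a
  # substantial share of the molecule's linking difference
  expect_gt(lk_loop / ch$delta_lk, 0.15)
  expect_error(loop_linking_number(ch, list(i = 10, j = 5)), "i < j")
})
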