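# shared fixtures and small oracles used across test files

default_params <- elastic_params()

# brute-force grid minimization of the mixed two-phase free energy over
# (sigma_s, sigma_p): independent oracle for the double-tangent solver
grid_coexistence <- function(force, params = default_params,
                             n_grid = 400) {
  # for the common tangent, minimize F(sigma) over partitions at a sigma in
  # the coexistence window; equivalently minimize over (ss, sp) the mixed
  # free energy at fixed sigma
  sigma <- 0.035
  ss_grid <- seq(0.002, sigma, length.out = n_grid)
  sp_grid <- seq(sigma, 0.12, length.out = n_grid)
  best <- c(Inf, NA, NA)
  for (ss in ss_grid) {
    S <- stretched_free_energy(ss, force, params)
    for (sp in sp_grid) {
      if (sp - ss < 1e-5) next
      nu <- (sp - sigma) / (sp - ss)
      if (nu < 0 || nu > 1) next
      f <- nu * S + (1 - nu) * plectoneme_free_energy(sp, params)
      if (f < best[1]) best <- c(f, ss, sp)
    }
  }
  list(sigma_s = best[2], sigma_p = best[3], F = best[1])
}

# fine-grid midpoint quadrature of the Gauss writhe integral for a closed
# polygonal curve (independent of the closed-form pairwise implementation)
writhe_quadrature <- function(P) {
  n <- nrow(P)
  Pn <- rbind(P, P[1, ])
  mid <- (Pn[-1, ] + Pn[-(n + 1), ]) / 2
  tg <- Pn[-1, ] - Pn[-(n + 1), ]
  s <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      r <- mid[i, ] - mid[j, ]
      d <- sum(r^2)^1.5
      cx <- c(tg[i, 2] * tg[j, 3] - tg[i, 3] * tg[j, 2],
              tg[i, 3] * tg[j, 1] - tg[i, 1] * tg[j, 3],
              tg[i, 1] * tg[j, 2] - tg[i, 2] * tg[j, 1])
      s <- s + sum(cx * r) / d
    }
  }
  2 * s / (4 * pi)
}

# smooth closed test curve with substantial writhe
torus_curve <- function(n, R = 10, r = 3, p = 5, q = 2) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind((R + r * cos(p * t)) * cos(q * t),
        (R + r * cos(p * t)) * sin(q * t),
        r * sin(p * t))
}

# small, fast MC chain for property tests
quick_chain <- function(n_bp = 600, delta_lk = 0, a = 5, ...) {
  dna_chain(n_bp, delta_lk = delta_lk, a = a, ...)
}
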