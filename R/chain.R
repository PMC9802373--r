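#' Discretized DNA chain at fixed linking number
#'
#' Builds a bead-chain representation of a torsionally constrained DNA
#' molecule for Monte Carlo simulation. The chain has `n_seg =
#' round(n_bp * helical_rise / a)` segments of exactly `a` nm; both terminal
#' tangents point along the stretching (z) axis. Twist is implicit: the fixed
#' linking difference `delta_lk` partitions into writhe (a property of the
#' bead positions) and uniform twist `Tw = delta_lk - Wr`.
#'
#' Two starting conformations are available: `"solenoid"` pre-stores most of
#' the linking difference as the writhe of a vertical superhelix (fast to
#' equilibrate in the postbuckling regime), `"straight"` starts from an
#' almost straight chain with all linking difference in twist.
#'
#' @param n_bp Number of base pairs.
#' @param delta_lk Linking difference (turns), fixed for the chain's lifetime.
#' @param params [elastic_params()].
#' @param a Segment (bead spacing) length, nm.
#' @param excluded_diameter Hard-core diameter between non-adjacent segments,
#'   nm (approximates electrostatic repulsion near 150 mM monovalent salt).
#' @param init Starting conformation: `"auto"` picks `"straight"` for small
#'   `|delta_lk|`, `"solenoid"` for intermediate and `"plectoneme"` (a
#'   pre-built interwound superhelix storing ~75% of `delta_lk` as writhe)
#'   for strongly supercoiled chains.
#' @param positions Optional N x 3 matrix of bead positions overriding
#'   `init` (must satisfy the chain invariants).
#' @return An object of class `dna_chain`: fields `positions`, `a`,
#'   `delta_lk`, `excluded_diameter`, `n_bp`, `L`, `params`.
#' @export
dna_chain <- function(n_bp, delta_lk, params = elastic_params(), a = 2.5,
                      excluded_diameter = 4,
                      init = c("auto", "straight", "solenoid", "plectoneme"),
                      force = NA_real_, positions = NULL) {
  params <- as_elastic_params(params)
  init <- match.arg(init)
  n_seg <- max(5L, round(n_bp * params$helical_rise / a))
  n_beads <- n_seg + 1L
  if (init == "auto") {
    init <- if (abs(delta_lk) <= 2) "straight"
            else if (abs(delta_lk) <= 4) "solenoid"
            else "plectoneme"
  }
  if (is.null(positions)) {
    positions <- switch(init,
      straight = init_straight(n_beads, a),
      solenoid = if (abs(delta_lk) > 1) init_solenoid(n_beads, a, delta_lk)
                 else init_straight(n_beads, a),
      plectoneme = init_plectoneme(n_beads, a, delta_lk, params = params,
                                   force = force, n_bp = n_bp))
  } else {
    positions <- as.matrix(positions)
    if (nrow(positions) != n_beads || ncol(positions) != 3) {
      stop("'positions' must be a ", n_beads, " x 3 matrix for this molecule")
    }
  }
  chain <- structure(
    list(positions = positions, a = a, delta_lk = delta_lk,
         excluded_diameter = excluded_diameter, n_bp = n_bp,
         L = n_seg * a, params = params),
    class = "dna_chain")
  validate_chain(chain)
  chain
}

# straight vertical chain with a tiny deterministic helical perturbation to
# break the rotational symmetry of the initial state
init_straight <- function(n_beads, a) {
  k <- seq_len(n_beads) - 1
  eps <- 0.05
  pos <- cbind(eps * cos(0.5 * k), eps * sin(0.5 * k), k * a)
  enforce_segment_lengths(pos, a)
}

# vertical solenoid storing ~70% of delta_lk as writhe: straight stem,
# superhelical section of radius r and per-turn climb h, straight top
init_solenoid <- function(n_beads, a, delta_lk) {
  r <- 8
  h <- 7
  ell <- sqrt((2 * pi * r)^2 + h^2)  # contour per superhelical turn
  L <- (n_beads - 1) * a
  n_turns <- min(0.7 * abs(delta_lk), 0.7 * L / ell)
  s_helix <- n_turns * ell
  s_stem <- (L - s_helix) / 2
  hand <- sign(delta_lk)
  path <- function(s) {
    # arc-length parametrized: stem, solenoid, stem
    if (s <= s_stem) return(c(0, 0, s))
    if (s >= s_stem + s_helix) {
      top <- path(s_stem + s_helix - 1e-9)
      return(c(top[1], top[2], top[3] + (s - s_stem - s_helix)))
    }
    u <- (s - s_stem) / ell  # turns completed
    phi <- 2 * pi * u * hand
    c(r * cos(phi) - r, r * sin(phi), s_stem + u * h)
  }
  fine <- t(vapply(seq(0, L + 10 * a, length.out = 40 * n_beads), path,
                   numeric(3)))
  pos <- resample_chord(fine, n_beads, a)
  pos <- enforce_segment_lengths(pos, a)
  # a mirror reflection flips the writhe sign; match it to delta_lk
  if (sign(cpp_writhe(pos, 1000 * L)) != sign(delta_lk)) pos[, 2] <- -pos[, 2]
  pos
}

# interwound plectoneme hanging from a junction on the stretched stem:
# stem up, connector out, one strand spiralling down a vertical superhelix
# axis, a tip turn, the second strand spiralling up phase-shifted by pi,
# connector back, stem up. Stores ~75% of delta_lk as writhe in a geometry
# close to the equilibrated postbuckling state.
init_plectoneme <- function(n_beads, a, delta_lk, params = elastic_params(),
                            force = NA_real_, n_bp = NULL) {
  L <- (n_beads - 1) * a
  hand <- sign(delta_lk)
  p <- 12                      # superhelical pitch per turn, nm
  ell_min <- sqrt(p^2 + (2 * pi * 3.5)^2)
  avail <- 0.85 * L - 95       # contour left for the two strands after the
                               # stems, connectors and tip are paid for
  if (avail < 3 * ell_min) {
    return(init_solenoid(n_beads, a, delta_lk))
  }
  # default geometry; refined below from the two-phase model when the force
  # is known, so the run starts near the equilibrium writhe and plectoneme
  # size (the tangent slope S'(sigma_s) sets the coexistence torque, hence
  # the equilibrium twist; the lever rule sets the plectonemic contour)
  n_t <- 0.75 * abs(delta_lk)
  ell <- min(58, avail / (2 * n_t))
  wr_target <- NULL
  lp_target <- NULL
  if (is.finite(force) && !is.null(n_bp)) {
    cx <- try(solve_coexistence(force, params), silent = TRUE)
    if (!inherits(cx, "try-error")) {
      Lk0 <- n_bp / params$helical_repeat
      sigma <- abs(delta_lk) / Lk0
      slope <- params$kBT * params$omega0^2 * mn_cs(force, params) *
        cx$sigma_s                               # dF/dsigma, pN
      torque <- slope / params$omega0            # pN nm
      tw_eq <- torque * L / (2 * pi * params$C * params$kBT)
      wr_target <- max(1.5, abs(delta_lk) - tw_eq)
      nu <- max(0, min(1, (cx$sigma_p - sigma) / (cx$sigma_p - cx$sigma_s)))
      lp_target <- max(120, (1 - nu) * L)
      n_t <- wr_target
      ell <- lp_target / (2 * n_t)
    }
  }
  clampgeo <- function(n_t, ell) {
    ell <- min(58, min(ell, avail / (2 * n_t)))
    if (ell < ell_min) {
      ell <- ell_min
      n_t <- min(n_t, avail / (2 * ell))
    }
    list(n_t = n_t, ell = ell)
  }
  g <- clampgeo(n_t, ell)
  n_t <- g$n_t
  ell <- g$ell
  build <- function(n_t, ell) {
  R <- sqrt(ell^2 - p^2) / (2 * pi)  # superhelix radius
  D <- 22 + R                        # lateral offset of the superhelix axis
  c_in <- 10
  E_x <- D + R + 6                   # overshoot of the horizontal approach
  len_leg2 <- sqrt(36 + c_in^2)
  len_out <- sqrt((D - R)^2 + (c_in + 6)^2)
  L_plect <- 2 * n_t * ell + pi * R + E_x + len_leg2 + len_out
  gap <- 6
  L_stem <- L - L_plect - gap
  if (L_stem < 4 * a) stop("chain too short to host the requested plectoneme")
  z_j <- 0.5 * L_stem
  # breakpoints in arc length
  s1 <- z_j                 # stem 1
  s1b <- s1 + E_x           # horizontal approach above the coils
  s2 <- s1b + len_leg2      # descent on the far side
  s3 <- s2 + n_t * ell      # strand down
  s4 <- s3 + pi * R         # tip half-turn
  s5 <- s4 + n_t * ell      # strand up
  s6 <- s5 + len_out        # connector out (+ gap in z)
  path <- function(s) {
    if (s <= s1) return(c(0, 0, s))
    if (s <= s1b) {
      u <- (s - s1) / E_x
      return(c(u * E_x, 0, z_j))
    }
    if (s <= s2) {
      u <- (s - s1b) / len_leg2
      return(c(E_x + u * (D + R - E_x), 0, z_j - u * c_in))
    }
    if (s <= s3) {
      tau <- (s - s2) / ell
      th <- 2 * pi * tau
      return(c(D + R * cos(th), hand * R * sin(th), z_j - c_in - tau * p))
    }
    if (s <= s4) {
      # tip: half-turn at the bottom, dipped downward to clear both strands
      th_e <- 2 * pi * n_t
      u <- (s - s3) / (pi * R)
      th <- th_e + u * pi
      return(c(D + R * cos(th), hand * R * sin(th),
               z_j - c_in - n_t * p - 9 * sin(pi * u)))
    }
    if (s <= s5) {
      tau <- (s - s4) / ell
      th <- 2 * pi * (n_t - tau) + pi
      return(c(D + R * cos(th), hand * R * sin(th),
               z_j - c_in - (n_t - tau) * p))
    }
    if (s <= s6) {
      # bowed out of the x-z plane so it cannot cross the entry legs
      u <- (s - s5) / len_out
      start <- c(D - R, 0, z_j - c_in)
      endp <- c(0, 0, z_j + gap)
      return(start + u * (endp - start) + c(0, 12 * sin(pi * u), 0))
    }
    c(0, 0, z_j + gap + (s - s6))
  }
  fine <- t(vapply(seq(0, L + 10 * a, length.out = 60 * n_beads), path,
                   numeric(3)))
  pos <- resample_chord(fine, n_beads, a)
  pos <- enforce_segment_lengths(pos, a)
  if (sign(cpp_writhe(pos, 1000 * L)) != sign(delta_lk)) pos[, 2] <- -pos[, 2]
  pos
  }
  pos <- build(n_t, ell)
  if (!is.null(wr_target)) {
    # one corrective rebuild: the writhe yield per built turn depends on the
    # geometry, so rescale the turn count to hit the equilibrium writhe
    yield <- abs(cpp_writhe(pos, 1000 * L)) / n_t
    if (is.finite(yield) && yield > 0.3) {
      g <- clampgeo(wr_target / yield, lp_target * yield / (2 * wr_target))
      pos2 <- try(build(g$n_t, g$ell), silent = TRUE)
      if (!inherits(pos2, "try-error")) pos <- pos2
    }
  }
  pos
}

# greedy resampling of a fine path at constant chord length a
resample_chord <- function(fine, n_beads, a) {
  pos <- matrix(0, n_beads, 3)
  pos[1, ] <- fine[1, ]
  idx <- 1L
  for (b in 2:n_beads) {
    cur <- pos[b - 1, ]
    while (idx < nrow(fine) &&
           sqrt(sum((fine[idx, ] - cur)^2)) < a) {
      idx <- idx + 1L
    }
    dirv <- fine[idx, ] - cur
    nd <- sqrt(sum(dirv^2))
    if (nd < 1e-12 || (idx >= nrow(fine) && nd < 1.5 * a)) {
      dirv <- c(0, 0, 1)  # past the end of the path: continue vertically
    } else {
      dirv <- dirv / nd
    }
    pos[b, ] <- cur + a * dirv
  }
  pos
}

# final pass guaranteeing |P[k+1] - P[k]| = a to machine precision
enforce_segment_lengths <- function(pos, a) {
  for (b in 2:nrow(pos)) {
    d <- pos[b, ] - pos[b - 1, ]
    nd <- sqrt(sum(d^2))
    if (nd < 1e-12) d <- c(0, 0, 1) else d <- d / nd
    pos[b, ] <- pos[b - 1, ] + a * d
  }
  pos
}

#' Validate the invariants of a chain conformation
#'
#' Checks equal segment lengths (1e-9 relative), self-avoidance of
#' non-adjacent segments, and terminal tangents along the stretching axis.
#'
#' @param chain A [dna_chain()].
#' @param check_excluded_volume Scan all non-adjacent segment pairs (O(N^2)).
#' @return Invisibly `TRUE`; errors describe the violated invariant.
#' @export
validate_chain <- function(chain, check_excluded_volume = TRUE) {
  pos <- chain$positions
  seglen <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                            pos[-nrow(pos), , drop = FALSE])^2))
  if (any(abs(seglen - chain$a) > 1e-9 * chain$a)) {
    stop("segment lengths deviate from a = ", chain$a, " nm")
  }
  t1 <- (pos[2, ] - pos[1, ]) / chain$a
  if (t1[3] < 0.8) stop("bottom tangent not aligned with the z axis")
  if (check_excluded_volume) {
    n_skip <- floor(2 * chain$excluded_diameter / chain$a + 1e-9)
    dmin <- cpp_min_nonadjacent_dist(pos, n_skip)
    if (dmin < chain$excluded_diameter * (1 - 1e-9)) {
      stop(sprintf(
        "self-avoidance violated: non-adjacent segments at %.3f nm < %.3f nm",
        dmin, chain$excluded_diameter))
    }
  }
  invisible(TRUE)
}

#' @export
print.dna_chain <- function(x, ...) {
  cat(sprintf(
    "twistable wormlike chain: %d beads (a = %.2f nm, L = %.1f nm)\n",
    nrow(x$positions), x$a, x$L))
  cat(sprintf("  delta_Lk = %.3f turns (sigma = %.4f), writhe = %.3f\n",
              x$delta_lk,
              x$delta_lk / (x$n_bp / x$params$helical_repeat), writhe(x)))
  invisible(x)
}

#' Writhe of a chain conformation
#'
#' Discretized Gauss double integral over all non-adjacent segment pairs,
#' using the exact closed-form solid-angle expression per straight segment
#' pair. Open chains use the axis-termination convention: both termini are
#' extended by long vertical rays (1000 L) before closure, so a planar
#' conformation has zero writhe and mirror reflection flips the sign.
#'
#' @param chain A [dna_chain()] or an N x 3 position matrix.
#' @param closed If `TRUE`, treat the rows as a closed polygon instead.
#' @return Writhe (turns).
#' @export
writhe <- function(chain, closed = FALSE) {
  pos <- if (inherits(chain, "dna_chain")) chain$positions else as.matrix(chain)
  if (nrow(pos) < 3) stop("need at least 3 beads")
  seglen <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                            pos[-nrow(pos), , drop = FALSE])^2))
  if (any(seglen < 1e-12)) stop("coincident consecutive beads")
  if (closed) {
    cpp_writhe_closed(pos)
  } else {
    L <- sum(seglen)
    cpp_writhe(pos, 1000 * L)
  }
}

#' Bending energy of a chain conformation
#'
#' `(A/a) * sum_i (1 - cos theta_i)` in units of kBT, with `theta_i` the
#' bend angle at interior joint i.
#'
#' @param chain A [dna_chain()].
#' @return Energy in kBT.
#' @export
bending_energy <- function(chain) {
  pos <- chain$positions
  tvec <- (pos[-1, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE]) / chain$a
  ct <- rowSums(tvec[-nrow(tvec), , drop = FALSE] * tvec[-1, , drop = FALSE])
  (chain$params$A / chain$a) * sum(1 - ct)
}

#' Twist energy of a chain conformation
#'
#' Implicit-twist convention: the twist `Tw = delta_lk - Wr` is distributed
#' uniformly along the chain, giving `(2 pi^2 C / L) (delta_lk - Wr)^2` in
#' kBT.
#'
#' @param chain A [dna_chain()].
#' @param wr Optionally a precomputed writhe (turns).
#' @return Energy in kBT.
#' @export
twist_energy <- function(chain, wr = NULL) {
  if (is.null(wr)) wr <- writhe(chain)
  2 * pi^2 * chain$params$C / chain$L * (chain$delta_lk - wr)^2
}

#' Label stretched and plectonemic beads
#'
#' A bead is plectonemic when another bead at contour separation greater than
#' `min_contour_sep` lies within `radius`; labels are smoothed by a 5-bead
#' majority vote. The contour partition is exact: `L_p + L_s = L`, with each
#' segment contributing half its length per labeled endpoint.
#'
#' @param chain A [dna_chain()].
#' @param min_contour_sep Minimum contour separation (nm) for a contact to
#'   count as superhelical rather than local; default four bend persistence
#'   lengths.
#' @param radius Contact radius (nm), about 1.5 times the superhelix radius.
#' @return List with `labels` (0 stretched / 1 plectonemic per bead),
#'   `L_p`, `L_s` (nm).
#' @export
detect_plectoneme <- function(chain, min_contour_sep = 4 * chain$params$A,
                              radius = 10) {
  lab <- cpp_plectoneme_labels(chain$positions, chain$a, min_contour_sep,
                               radius)
  n <- length(lab)
  lp <- sum(0.5 * chain$a * (lab[-n] + lab[-1]))
  list(labels = lab, L_p = lp, L_s = chain$L - lp)
}

#' Candidate bridge sites on a plectoneme
#'
#' Finds bead pairs mimicking the two binding sites of a DNA-bridging
#' protein: both beads plectonemic, mutual distance below `threshold`, and
#' lying on opposite superhelical strands (antiparallel tangents,
#' `t_i . t_j < tangent_dot_max`). Each pair is annotated with the looped
#' contour length `delta_L` it would trap.
#'
#' @param chain An equilibrated postbuckling [dna_chain()] conformation.
#' @param threshold Maximum site-site distance, nm.
#' @param tangent_dot_max Upper bound on the tangent dot product for the
#'   opposite-strand test.
#' @return A data.frame with columns `i`, `j` (bead indices, i < j), `dist`
#'   (nm), `delta_L` (nm); zero rows when no plectoneme is present.
#' @export
select_bridge_sites <- function(chain, threshold = 8,
                                tangent_dot_max = -0.5) {
  pos <- chain$positions
  n <- nrow(pos)
  lab <- detect_plectoneme(chain)$labels
  tvec <- (pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]) / chain$a
  res <- list()
  # candidate site beads need a defined tangent: beads 2..n-1 (1-based)
  cand <- which(lab == 1L)
  cand <- cand[cand >= 2 & cand <= n - 1]
  if (length(cand) >= 2) {
    for (ii in seq_along(cand)) {
      i <- cand[ii]
      for (j in cand[-seq_len(ii)]) {
        if (j - i < 4) next
        d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
        if (d >= threshold) next
        if (sum(tvec[i, ] * tvec[j, ]) >= tangent_dot_max) next
        res[[length(res) + 1L]] <- c(i, j, d, (j - i) * chain$a)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(i = integer(), j = integer(), dist = numeric(),
                      delta_L = numeric()))
  }
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("i", "j", "dist", "delta_L")
  out$i <- as.integer(out$i)
  out$j <- as.integer(out$j)
  out[order(out$delta_L), ]
}

#' Linking number trapped in a bridged loop
#'
#' The loop subchain (beads `i..j`, closed by the short chord across the
#' bridge) carries a writhe plus its share of the uniformly distributed
#' implicit twist: `Lk_loop = Wr_loop + (delta_lk - Wr_total) * delta_L / L`.
#'
#' @param chain A bridged [dna_chain()] conformation.
#' @param bridge List or one-row data.frame with bead indices `i` and `j`.
#' @return Linking number of the looped domain (turns).
#' @export
loop_linking_number <- function(chain, bridge) {
  i <- as.integer(bridge$i)
  j <- as.integer(bridge$j)
  if (length(i) != 1L || length(j) != 1L || is.na(i) || is.na(j) ||
      i < 1 || j <= i || j > nrow(chain$positions)) {
    stop("'bridge' must supply bead indices i < j within the chain")
  }
  wr_loop <- cpp_writhe_closed(chain$positions[i:j, , drop = FALSE])
  wr_tot <- writhe(chain)
  dl <- (j - i) * chain$a
  wr_loop + (chain$delta_lk - wr_tot) * dl / chain$L
}
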