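#' Run a fixed-linking-number Monte Carlo simulation
#'
#' Metropolis sampling of the twistable wormlike chain under tension:
#' crankshaft rotations of interior subchains and pivot rotations of a short
#' top tail, with hard-core excluded volume (sub-stepped sweep checks plus an
#' exact segment-segment check), a `|dWr| > 0.5` strand-passage sentinel, and
#' implicit twist energy at fixed `delta_lk`. Reproducible given `seed`.
#'
#' @param chain A [dna_chain()]; also used as the starting conformation.
#' @param force Stretching force (pN).
#' @param n_steps Number of Monte Carlo steps after equilibration.
#' @param seed Integer seed for the simulation RNG.
#' @param equil Equilibration steps discarded before sampling.
#' @param stride Record one sample every `stride` steps.
#' @param bridge Optional bridge constraint: list or one-row data.frame with
#'   bead indices `i`, `j` (e.g. one row of [select_bridge_sites()] output).
#'   The relative position and orientation of the two site beads is kept
#'   fixed throughout, trapping the looped domain between them.
#' @param theta_crank,theta_pivot Maximum rotation angles (rad); pivot
#'   angles additionally shrink with the square root of the tail length.
#' @param max_move_beads Maximum interior beads moved per crankshaft.
#' @param max_pivot_beads Maximum tail length for pivot moves.
#' @param p_pivot Probability of proposing a short top-tail pivot.
#' @param p_pivot_long Probability of a pivot based anywhere on the chain
#'   (rotates the whole upper part; expensive but moves extension in large
#'   strides).
#' @return An object of class `mc_ensemble`: `samples` (data.frame with
#'   `step`, `z`, `wr`, `lp`, and `loop_lk` for bridged runs), `acceptance`
#'   counters, the final `chain`, and run metadata.
#' @examples
#' \donttest{
#' ch <- dna_chain(600, delta_lk = 0, a = 5)
#' ens <- mc_run(ch, force = 2, n_steps = 2e4, seed = 1)
#' summary(ens)
#' }
#' @export
mc_run <- function(chain, force, n_steps, seed, equil = 0,
                   stride = 1000, bridge = NULL,
                   theta_crank = pi / 2, theta_pivot = 0.9,
                   max_move_beads = 14, max_pivot_beads = 60,
                   p_pivot = 0.25, p_pivot_long = 0.05) {
  stopifnot(inherits(chain, "dna_chain"))
  if (n_steps < stride) stop("'n_steps' must be at least 'stride'")
  bi <- bj <- -1L
  if (!is.null(bridge)) {
    bi <- as.integer(bridge$i)
    bj <- as.integer(bridge$j)
  }
  p <- chain$params
  res <- cpp_mc_run(chain$positions, chain$a, chain$delta_lk,
                    p$A, p$C, p$kBT, force, chain$excluded_diameter,
                    as.double(n_steps), as.integer(stride), as.double(equil),
                    as.integer(seed), theta_crank, theta_pivot,
                    as.integer(max_move_beads), as.integer(max_pivot_beads),
                    p_pivot, p_pivot_long,
                    bi, bj,
                    10 * p$A / chain$a, 4 * p$A, 10)
  final <- chain
  final$positions <- res$positions
  samples <- data.frame(step = res$step, z = res$z, wr = res$wr, lp = res$lp,
                        loop_lk = res$loop_lk)
  out <- structure(
    list(samples = samples, acceptance = res$acceptance, chain = final,
         force = force, seed = seed, n_steps = n_steps, stride = stride,
         equil = equil, bridge = bridge, wr_final = res$wr_final),
    class = "mc_ensemble")
  eq <- equilibration_diagnostic(samples$z)
  if (!eq$ok) {
    warning(sprintf(
      "possible non-equilibration: block means of z drift by %.1f nm (%.1f SE)",
      eq$drift, eq$drift / eq$se))
  }
  out$equilibration <- eq
  out
}

#' Run a bridged (protein-constrained) simulation
#'
#' Thin wrapper over [mc_run()] that requires a bridge constraint; moves that
#' would alter the relative pose of the two bridged site beads are rejected,
#' so the looped domain between them is a fixed topological domain.
#'
#' @inheritParams mc_run
#' @param bridge A bridge site pair (row of [select_bridge_sites()]).
#' @return An `mc_ensemble` with `loop_lk` samples filled in.
#' @export
mc_run_bridged <- function(chain, bridge, force, n_steps, seed, ...) {
  if (is.null(bridge) || is.null(bridge$i) || is.null(bridge$j)) {
    stop("'bridge' must supply site bead indices i and j")
  }
  mc_run(chain, force = force, n_steps = n_steps, seed = seed,
         bridge = bridge, ...)
}

#' Simulate a ladder of linking numbers
#'
#' Runs the chain at a series of increasing linking differences, reusing the
#' final conformation of each run (with its accumulated writhe) as the start
#' of the next. This anneals the plectoneme gradually and is much cheaper to
#' equilibrate than independent runs. Returns one ensemble per rung.
#'
#' @param n_bp Molecule size (bp).
#' @param delta_lks Increasing linking differences (turns).
#' @param force Stretching force (pN).
#' @param n_steps Sampling steps per rung.
#' @param equil Equilibration steps per rung.
#' @param seed Integer seed; rung r uses `seed + r - 1`.
#' @param a Bead spacing (nm).
#' @param ... Passed to [mc_run()].
#' @return List of `mc_ensemble` objects, names `dLk=<value>`.
#' @export
mc_ladder <- function(n_bp, delta_lks, force, n_steps, equil, seed,
                      a = 2.5, ...) {
  if (is.unsorted(delta_lks)) stop("'delta_lks' must be increasing")
  out <- vector("list", length(delta_lks))
  names(out) <- paste0("dLk=", signif(delta_lks, 4))
  chain <- dna_chain(n_bp, delta_lks[1], a = a, force = force)
  for (r in seq_along(delta_lks)) {
    chain$delta_lk <- delta_lks[r]
    out[[r]] <- mc_run(chain, force = force, n_steps = n_steps,
                       equil = equil, seed = seed + r - 1, ...)
    chain <- out[[r]]$chain
  }
  out
}

# drift check: difference of first/last third block means vs block SE
equilibration_diagnostic <- function(z, n_blocks = 12) {
  n <- length(z)
  if (n < 3 * n_blocks) {
    return(list(ok = TRUE, drift = 0, se = Inf))
  }
  bm <- tapply(z, cut(seq_len(n), n_blocks, labels = FALSE), mean)
  k <- max(2L, floor(n_blocks / 3))
  drift <- abs(mean(bm[seq_len(k)]) - mean(bm[n_blocks - seq_len(k) + 1]))
  se <- sd(bm) / sqrt(k)
  list(ok = drift < 4 * se, drift = drift, se = se)
}

#' Block-averaged standard error
#'
#' Standard error of the mean of a correlated series, from the variance of
#' `n_blocks` contiguous block means.
#'
#' @param x Numeric series.
#' @param n_blocks Number of blocks.
#' @return Standard error of `mean(x)`.
#' @export
block_se <- function(x, n_blocks = 10) {
  n <- length(x)
  if (n < 2 * n_blocks) n_blocks <- max(2L, floor(n / 2))
  bm <- tapply(x, cut(seq_len(n), n_blocks, labels = FALSE), mean)
  sd(bm) / sqrt(length(bm))
}

#' @export
summary.mc_ensemble <- function(object, ...) {
  s <- object$samples
  out <- list(
    n_samples = nrow(s),
    force = object$force,
    delta_lk = object$chain$delta_lk,
    z_mean = mean(s$z), z_se = block_se(s$z),
    z_var = var(s$z), z_var_se = block_se((s$z - mean(s$z))^2),
    wr_mean = mean(s$wr), wr_se = block_se(s$wr),
    lp_mean = mean(s$lp), lp_se = block_se(s$lp),
    acceptance_rate =
      (object$acceptance$accepted_crankshaft +
         object$acceptance$accepted_pivot) /
      max(1, object$acceptance$proposed_crankshaft +
            object$acceptance$proposed_pivot))
  if (!all(is.na(s$loop_lk))) {
    out$loop_lk_mean <- mean(s$loop_lk)
    out$loop_lk_var <- var(s$loop_lk)
  }
  class(out) <- "summary.mc_ensemble"
  out
}

#' @export
print.summary.mc_ensemble <- function(x, ...) {
  cat(sprintf("MC ensemble: %d samples at f = %.3g pN, dLk = %.3f\n",
              x$n_samples, x$force, x$delta_lk))
  cat(sprintf("  <z>    = %8.2f +/- %.2f nm\n", x$z_mean, x$z_se))
  cat(sprintf("  <dz^2> = %8.1f nm^2\n", x$z_var))
  cat(sprintf("  <Wr>   = %8.3f +/- %.3f turns\n", x$wr_mean, x$wr_se))
  cat(sprintf("  <L_p>  = %8.1f +/- %.1f nm\n", x$lp_mean, x$lp_se))
  if (!is.null(x$loop_lk_mean)) {
    cat(sprintf("  loop Lk: mean %.3f, var %.4f turns^2\n",
                x$loop_lk_mean, x$loop_lk_var))
  }
  cat(sprintf("  acceptance rate %.2f\n", x$acceptance_rate))
  invisible(x)
}

#' @export
print.mc_ensemble <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
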