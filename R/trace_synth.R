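#' Statistical model of a bead-tracking extension trace
#'
#' Describes the stationary statistics of a magnetic-tweezers extension
#' signal as an Ornstein-Uhlenbeck process in a harmonic well: mean, variance
#' and correlation time. The implied bead friction follows from the harmonic
#' relation `tau_c = (gamma / kBT) * <dz^2>`.
#'
#' @param mean Mean extension (nm).
#' @param variance Extension variance (nm^2), > 0.
#' @param tau_c Autocorrelation time (s), > 0.
#' @param rate Acquisition rate (Hz).
#' @param duration Trace duration (s).
#' @param temperature Temperature (K), for the friction coefficient.
#' @return An object of class `trace_model` (fields include `gamma`,
#'   pN s/nm).
#' @export
trace_model <- function(mean, variance, tau_c, rate = 1000, duration = 60,
                        temperature = 298) {
  if (variance <= 0) stop("'variance' must be positive")
  if (tau_c <= 0) stop("'tau_c' must be positive")
  if (rate <= 0 || duration <= 0) stop("rate and duration must be positive")
  if (rate * duration < 1000) {
    stop("trace too short: need at least 1000 samples (rate * duration)")
  }
  kBT <- 0.0138064852 * temperature
  structure(
    list(mean = mean, variance = variance, tau_c = tau_c, rate = rate,
         duration = duration, kBT = kBT,
         gamma = kBT * tau_c / variance),
    class = "trace_model")
}

#' @export
print.trace_model <- function(x, ...) {
  cat(sprintf(
    "trace model: mean %.1f nm, var %.1f nm^2, tau_c %.3g s @ %g Hz x %g s\n",
    x$mean, x$variance, x$tau_c, x$rate, x$duration))
  cat(sprintf("  implied friction gamma = %.3g pN s/nm\n", x$gamma))
  invisible(x)
}

#' Markov model of discrete extension states
#'
#' Describes transitions among discrete linking-number states of a bridged
#' (looped) DNA molecule. Dissociation/rebinding events occur at rate
#' `1/tau_p`; at each event the destination state is drawn from the
#' stationary occupancies `p_i` (self-transitions allowed), so the observed
#' dwell time in state i is exponential with mean `tau_i = tau_p / (1 -
#' p_i)`. Occupancies are Gaussian in the loop linking-number change
#' `ddlk`, with variance `delta_L / (4 pi^2 P)`.
#'
#' @param ddlk Integer vector of loop linking-number states (turns, relative
#'   to the most populated level), e.g. `-2:2`.
#' @param occupancy Optional explicit occupancies (normalized internally);
#'   default Gaussian from `delta_L` and `P`.
#' @param delta_L Looped DNA length (nm) used for the Gaussian occupancies.
#' @param P Plectoneme torsional stiffness (nm).
#' @param tau_p Characteristic loop dissociation/reformation time (s).
#' @param spacing Extension change per trapped turn (nm/turn).
#' @param base_extension Mean extension of the `ddlk = 0` state (nm).
#' @return An object of class `switching_model` with `levels` (data.frame:
#'   `ddlk`, `z`, `p`, `tau_dwell`) and `tau_p`.
#' @export
switching_model <- function(ddlk = -2:2, occupancy = NULL,
                            delta_L = 254, P = 20, tau_p = 65,
                            spacing = 48, base_extension = 800) {
  if (anyDuplicated(ddlk)) stop("'ddlk' must be distinct")
  if (is.null(occupancy)) {
    v <- delta_L / (4 * pi^2 * P)
    occupancy <- exp(-ddlk^2 / (2 * v))
  }
  if (length(occupancy) != length(ddlk) || any(occupancy < 0)) {
    stop("'occupancy' must be non-negative and match 'ddlk'")
  }
  p <- occupancy / sum(occupancy)
  # extension DROPS when the loop traps an extra positive turn: that turn is
  # removed from the unlooped DNA, shortening its plectoneme
  levels <- data.frame(ddlk = ddlk, z = base_extension - spacing * ddlk,
                       p = p, tau_dwell = tau_p / (1 - p))
  structure(list(levels = levels, tau_p = tau_p, spacing = spacing,
                 delta_L = delta_L, P = P),
            class = "switching_model")
}

#' @export
print.switching_model <- function(x, ...) {
  cat(sprintf("switching model: %d states, tau_p = %.3g s, spacing %.3g nm\n",
              nrow(x$levels), x$tau_p, x$spacing))
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' Generate an Ornstein-Uhlenbeck extension trace
#'
#' Exact discretization of the stationary OU process at the acquisition
#' rate: `z[t+1] = mean + phi (z[t] - mean) + e`, `phi = exp(-dt/tau_c)`,
#' `e ~ N(0, variance (1 - phi^2))`, with `z[1]` drawn from the stationary
#' distribution, so the trace is stationary from the first sample.
#'
#' @param model A [trace_model()].
#' @param seed Integer seed.
#' @param force,sigma Metadata stored with the trace (pN, dimensionless).
#' @return An `extension_trace` object (see [extension_trace()]).
#' @export
generate_ou_trace <- function(model, seed, force = NA_real_,
                              sigma = NA_real_) {
  stopifnot(inherits(model, "trace_model"))
  n <- round(model$rate * model$duration)
  dt <- 1 / model$rate
  phi <- exp(-dt / model$tau_c)
  sdev <- sqrt(model$variance)
  z <- ou_path(n, phi, sdev, seed)
  extension_trace(time = (seq_len(n) - 1) * dt, z = model$mean + z,
                  rate = model$rate, force = force, sigma = sigma,
                  provenance = "synthetic-ou")
}

# stationary OU path with zero mean and unit-lag autoregression phi
ou_path <- function(n, phi, sdev, seed, rng_reserved = FALSE) {
  if (!rng_reserved) set.seed(seed)
  innov <- rnorm(n, sd = sdev * sqrt(1 - phi^2))
  innov[1] <- rnorm(1, sd = sdev)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Generate a state-switching extension trace
#'
#' Continuous-time Markov switching among the discrete extension levels of a
#' [switching_model()] (dissociation/rebinding events at rate `1/tau_p`,
#' destination drawn from the stationary occupancies with self-transitions
#' allowed), with stationary Ornstein-Uhlenbeck noise from a [trace_model()]
#' superposed. The ground-truth state path is returned alongside the
#' observations for recovery tests.
#'
#' @param switching A [switching_model()].
#' @param base A [trace_model()] for the superposed noise (its mean is
#'   ignored; level means come from `switching`).
#' @param seed Integer seed.
#' @param force,sigma Metadata stored with the trace.
#' @return An `extension_trace` whose `state` column holds the true level
#'   index (row of `switching$levels`).
#' @export
generate_switching_trace <- function(switching, base, seed,
                                     force = NA_real_, sigma = NA_real_) {
  stopifnot(inherits(switching, "switching_model"),
            inherits(base, "trace_model"))
  n <- round(base$rate * base$duration)
  dt <- 1 / base$rate
  set.seed(seed)
  lv <- switching$levels
  # event times: Poisson with rate 1/tau_p; destinations iid from p
  t_end <- base$duration
  n_ev_guess <- ceiling(1.5 * t_end / switching$tau_p + 20)
  ev <- cumsum(rexp(n_ev_guess, rate = 1 / switching$tau_p))
  while (sum(ev <= t_end) == length(ev)) {
    ev <- c(ev, ev[length(ev)] + cumsum(rexp(n_ev_guess,
                                             rate = 1 / switching$tau_p)))
  }
  ev <- ev[ev <= t_end]
  dest <- sample.int(nrow(lv), length(ev) + 1L, replace = TRUE, prob = lv$p)
  # piecewise-constant state path sampled at the acquisition grid
  tgrid <- (seq_len(n) - 1) * dt
  state <- dest[findInterval(tgrid, ev) + 1L]
  noise <- ou_path(n, exp(-dt / base$tau_c), sqrt(base$variance), seed,
                   rng_reserved = TRUE)
  extension_trace(time = tgrid, z = lv$z[state] + noise, rate = base$rate,
                  force = force, sigma = sigma,
                  provenance = "synthetic-switching", state = state)
}

#' Generate noisy rotation curves from the two-phase model
#'
#' Evaluates the analytical mean extension and extension variance on a
#' supercoiling-density grid for each force and adds Gaussian measurement
#' noise with a stated relative standard deviation; used to exercise the
#' fitting and extrapolation stages.
#'
#' @param forces Forces (pN).
#' @param sigma_grid Supercoiling densities (non-negative, increasing).
#' @param molecule A [molecule_spec()].
#' @param rel_noise Relative noise SD applied to both curves (0 = exact
#'   theory values).
#' @param seed Integer seed.
#' @return Named list of `rotation_curve` objects, one per force.
#' @export
generate_rotation_dataset <- function(forces, sigma_grid, molecule,
                                      rel_noise = 0.02, seed = 1) {
  stopifnot(inherits(molecule, "molecule_spec"))
  set.seed(seed)
  out <- lapply(forces, function(f) {
    cv <- theory_rotation_curve(sigma_grid, f, molecule)
    se_z <- rel_noise * abs(cv$z)
    se_v <- rel_noise * abs(cv$var_z)
    rotation_curve(sigma = cv$sigma,
                   z = cv$z + rnorm(length(se_z), sd = se_z),
                   var_z = cv$var_z + rnorm(length(se_v), sd = se_v),
                   se_z = se_z, se_var = se_v,
                   force = f, molecule = molecule)
  })
  names(out) <- paste0("f=", signif(forces, 3))
  out
}
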