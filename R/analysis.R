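#' Extension time trace
#'
#' Container for a bead-tracking extension time series at known acquisition
#' rate, force and supercoiling density. Sampling must be uniform (1 ppm),
#' values finite.
#'
#' @param time Time stamps (s), uniformly spaced.
#' @param z Extension (nm).
#' @param rate Acquisition rate (Hz); checked against `time`.
#' @param force Force (pN) or `NA`.
#' @param sigma Supercoiling density or `NA`.
#' @param provenance Free-text origin label.
#' @param state Optional ground-truth state path (integer per sample).
#' @return An object of class `extension_trace`.
#' @export
extension_trace <- function(time, z, rate, force = NA_real_,
                            sigma = NA_real_, provenance = "unknown",
                            state = NULL) {
  if (length(time) != length(z)) stop("'time' and 'z' lengths differ")
  if (!is.null(state) && length(state) != length(z)) {
    stop("'state' length differs from 'z'")
  }
  if (anyNA(z) || any(!is.finite(z))) stop("non-finite extension values")
  if (!is.numeric(rate) || rate <= 0) stop("'rate' must be positive")
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("time stamps not strictly increasing")
    if (max(abs(dt - 1 / rate)) > 1e-6 / rate) {
      stop("non-uniform sampling (beyond 1 ppm of the stated rate)")
    }
  }
  structure(list(time = time, z = z, rate = rate, force = force,
                 sigma = sigma, provenance = provenance, state = state),
            class = "extension_trace")
}

#' @export
print.extension_trace <- function(x, ...) {
  cat(sprintf(
    "extension trace: %d samples @ %g Hz (%.4g s), f = %s pN, sigma = %s\n",
    length(x$z), x$rate, length(x$z) / x$rate,
    format(x$force), format(x$sigma)))
  cat(sprintf("  mean %.2f nm, sd %.2f nm  [%s]\n",
              mean(x$z), sd(x$z), x$provenance))
  invisible(x)
}

#' Rotation curve container
#'
#' Mean extension and extension variance versus supercoiling density at one
#' force, with per-point standard errors, from theory, simulation or
#' measurement.
#'
#' @param sigma Strictly increasing supercoiling densities.
#' @param z Mean extensions (nm).
#' @param var_z Extension variances (nm^2).
#' @param se_z,se_var Standard errors (>= 0).
#' @param force Force (pN).
#' @param molecule A [molecule_spec()].
#' @return A data.frame of class `rotation_curve` with attributes `force`
#'   and `molecule`.
#' @export
rotation_curve <- function(sigma, z, var_z, se_z, se_var, force, molecule) {
  stopifnot(inherits(molecule, "molecule_spec"))
  if (is.unsorted(sigma, strictly = TRUE)) {
    stop("'sigma' must be strictly increasing")
  }
  if (any(se_z < 0) || any(se_var < 0)) stop("standard errors must be >= 0")
  out <- data.frame(sigma = sigma, z = z, var_z = var_z,
                    se_z = se_z, se_var = se_var)
  attr(out, "force") <- force
  attr(out, "molecule") <- molecule
  class(out) <- c("rotation_curve", "data.frame")
  out
}

#' Windowed mean and variance of a trace
#'
#' Splits the trace into non-overlapping windows, removes the window mean
#' (suppressing slow drift) and pools the per-window unbiased variances; the
#' standard errors come from the scatter of window statistics.
#'
#' @param trace An [extension_trace()].
#' @param window_s Window length (s); must contain at least 10 samples.
#' @return List: `windows` (data.frame `t_mid`, `mean`, `var`),
#'   `mean`, `mean_se`, `var`, `var_se`, `n_windows`.
#' @export
windowed_stats <- function(trace, window_s = 1.0) {
  stopifnot(inherits(trace, "extension_trace"))
  w <- round(window_s * trace$rate)
  if (w < 10) stop("window shorter than 10 samples")
  n <- length(trace$z)
  k <- n %/% w
  if (k < 2) stop("trace shorter than 2 windows")
  zm <- matrix(trace$z[seq_len(k * w)], nrow = w)
  mu <- colMeans(zm)
  v <- colSums((zm - rep(mu, each = w))^2) / (w - 1)
  t_mid <- trace$time[1] + (seq_len(k) - 0.5) * w / trace$rate
  list(windows = data.frame(t_mid = t_mid, mean = mu, var = v),
       mean = mean(mu), mean_se = sd(mu) / sqrt(k),
       var = mean(v), var_se = sd(v) / sqrt(k),
       n_windows = k)
}

#' Autocorrelation time of a trace
#'
#' Integral of the normalized autocorrelation function up to its first zero
#' crossing (`tau_c = dt * (1/2 + sum rho_k)`), computed by FFT on at most
#' 2^21 samples. For an Ornstein-Uhlenbeck signal this reproduces the
#' exponential correlation time.
#'
#' @param trace An [extension_trace()].
#' @param max_lag_s Largest lag considered (s).
#' @return List: `tau_c` (s), `n_lags` used, `decaying` (FALSE when no zero
#'   crossing was found, flagged with a warning).
#' @export
autocorrelation_time <- function(trace, max_lag_s = NULL) {
  stopifnot(inherits(trace, "extension_trace"))
  z <- trace$z
  if (length(z) > 2^21) z <- z[seq_len(2^21)]
  n <- length(z)
  dt <- 1 / trace$rate
  if (is.null(max_lag_s)) max_lag_s <- n * dt / 10
  kmax <- max(2L, min(n - 1L, round(max_lag_s / dt)))
  x <- z - mean(z)
  npad <- 2^ceiling(log2(n + kmax))
  f <- fft(c(x, rep(0, npad - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(kmax + 1)]
  rho <- ac / ac[1]
  zero <- which(rho <= 0)[1]
  decaying <- !is.na(zero)
  if (!decaying) {
    warning("autocorrelation does not decay to zero within the lag window")
    zero <- kmax + 1
  }
  tau <- dt * (0.5 + if (zero > 2) sum(rho[2:(zero - 1)]) else 0)
  list(tau_c = tau, n_lags = zero - 1, decaying = decaying)
}

#' Fit the two regimes of a rotation curve
#'
#' Fits the prebuckling branch of the mean extension quadratically (even in
#' sigma) and the postbuckling branch linearly, choosing the split that
#' minimizes the total residual sum of squares; the buckling density is the
#' intersection of the two branches. The variance curve is fit with the same
#' split.
#'
#' @param curve A [rotation_curve()] spanning both regimes.
#' @return List of class `rotation_fit`: `sigma_buckling`, `pre`
#'   (quadratic coefficients for z), `post` (linear fit for z:
#'   `slope`, `intercept`, `slope_se`, `slope_per_turn` in nm/turn),
#'   `var_post` (linear fit for the variance), `diagnostics`.
#' @export
fit_rotation_curve <- function(curve) {
  stopifnot(inherits(curve, "rotation_curve"))
  n <- nrow(curve)
  if (n < 7) stop("need at least 7 points to resolve both regimes")
  s <- curve$sigma
  # candidate splits: at least 3 points per branch
  best <- NULL
  for (k in 3:(n - 3)) {
    pre <- lm(z ~ I(sigma^2), data = curve[1:k, ])
    post <- lm(z ~ sigma, data = curve[(k + 1):n, ])
    rss <- sum(resid(pre)^2) + sum(resid(post)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(k = k, rss = rss, pre = pre, post = post)
    }
  }
  cp <- coef(best$pre)   # z = a + b sigma^2
  cl <- coef(best$post)  # z = c + d sigma
  disc <- cl[2]^2 - 4 * cp[2] * (cp[1] - cl[1])
  sigma_b <- if (is.na(disc) || disc < 0) {
    s[best$k]  # branches do not intersect cleanly; use the split point
  } else {
    r <- (cl[2] + c(-1, 1) * sqrt(disc)) / (2 * cp[2])
    r[which.min(abs(r - s[best$k]))]
  }
  monotone_ok <- best$k > 3 || cp[2] < 0
  if (!monotone_ok) {
    warning("buckling not clearly detectable from this curve")
  }
  mol <- attr(curve, "molecule")
  post_sum <- suppressWarnings(summary(best$post))
  vpost <- lm(var_z ~ sigma, data = curve[(best$k + 1):n, ])
  vpre <- lm(var_z ~ I(sigma^2), data = curve[1:best$k, ])
  structure(list(
    sigma_buckling = unname(sigma_b),
    split_index = best$k,
    pre = list(intercept = unname(cp[1]), curvature = unname(cp[2]),
               fit = best$pre),
    post = list(intercept = unname(cl[1]), slope = unname(cl[2]),
                slope_se = post_sum$coefficients[2, 2],
                slope_per_turn = unname(abs(cl[2])) / mol$Lk0,
                fit = best$post),
    var_pre = list(curvature = unname(coef(vpre)[2]), fit = vpre),
    var_post = list(intercept = unname(coef(vpost)[1]),
                    slope = unname(coef(vpost)[2]), fit = vpost),
    diagnostics = list(rss = best$rss, detectable = monotone_ok),
    force = attr(curve, "force"), molecule = mol), class = "rotation_fit")
}

#' @export
print.rotation_fit <- function(x, ...) {
  cat(sprintf("rotation-curve fit at f = %.3g pN\n", x$force))
  cat(sprintf("  buckling at sigma = %.4f\n", x$sigma_buckling))
  cat(sprintf("  prebuckling curvature %.1f nm per unit sigma^2\n",
              x$pre$curvature))
  cat(sprintf("  postbuckling slope %.1f nm (%.1f nm/turn)\n",
              x$post$slope, x$post$slope_per_turn))
  invisible(x)
}

#' Calibrate the fluctuation-to-domain-size conversion
#'
#' From postbuckling rotation data: the plectonemic density `sigma_p` is the
#' zero-extension intercept of the linear extension fit, and the variance
#' factor `kappa` is the linear variance fit extrapolated to `sigma_p`,
#' divided by the contour length. `kappa` (nm^2 per nm) converts a variance
#' drop into looped DNA length. Works identically on theory, Monte Carlo or
#' experimental-style curves.
#'
#' @param curve A postbuckling [rotation_curve()] (>= 4 points); points below
#'   `sigma_min` are dropped first.
#' @param sigma_min Optional lower cutoff, e.g. buckling density + 0.005.
#' @param var_sigma_max Optional upper cutoff for the variance fit only: the
#'   variance is extrapolated from the window where it still increases
#'   linearly with sigma (short molecules flatten out early by finite size).
#' @param n_boot Parametric bootstrap replicates for the confidence
#'   intervals (resampling points from their standard errors).
#' @return Object of class `fluct_calibration`: `sigma_p`, `kappa`,
#'   `slope_per_turn` (nm/turn), standard errors, fit ranges, diagnostics.
#' @export
calibrate_fluctuations <- function(curve, sigma_min = NULL,
                                   var_sigma_max = NULL, n_boot = 200) {
  stopifnot(inherits(curve, "rotation_curve"))
  if (!is.null(sigma_min)) curve <- curve[curve$sigma >= sigma_min, ]
  if (nrow(curve) < 4) stop("need at least 4 postbuckling points")
  mol <- attr(curve, "molecule")
  vsel <- if (is.null(var_sigma_max)) rep(TRUE, nrow(curve))
          else curve$sigma <= var_sigma_max
  if (sum(vsel) < 2) stop("variance window retains fewer than 2 points")
  core <- function(z, v) {
    fz <- lm(z ~ curve$sigma)
    sp <- -coef(fz)[1] / coef(fz)[2]
    fv <- lm(v[vsel] ~ curve$sigma[vsel])
    kap <- (coef(fv)[1] + coef(fv)[2] * sp) / mol$L
    c(sigma_p = unname(sp), kappa = unname(kap),
      slope_per_turn = unname(abs(coef(fz)[2])) / mol$Lk0)
  }
  est <- core(curve$z, curve$var_z)
  boot <- NULL
  if (n_boot > 0 && any(curve$se_z > 0 | curve$se_var > 0)) {
    boot <- t(replicate(n_boot, core(
      curve$z + rnorm(nrow(curve), sd = curve$se_z),
      curve$var_z + rnorm(nrow(curve), sd = curve$se_var))))
  }
  se <- if (is.null(boot)) c(sigma_p = 0, kappa = 0, slope_per_turn = 0)
        else apply(boot, 2, sd)
  span <- diff(range(curve$sigma))
  flag_extrap <- est["sigma_p"] > max(curve$sigma) + span
  if (flag_extrap) {
    warning("sigma_p lies beyond twice the fitted sigma range; ",
            "extrapolation may be unreliable")
  }
  if (est["sigma_p"] <= max(curve$sigma)) {
    warning("fitted sigma_p does not exceed the largest sigma in the data")
  }
  structure(list(
    sigma_p = unname(est["sigma_p"]), sigma_p_se = unname(se["sigma_p"]),
    kappa = unname(est["kappa"]), kappa_se = unname(se["kappa"]),
    slope_per_turn = unname(est["slope_per_turn"]),
    slope_per_turn_se = unname(se["slope_per_turn"]),
    fit_range = range(curve$sigma), n_points = nrow(curve),
    extrapolation_flag = unname(flag_extrap),
    force = attr(curve, "force"), molecule = mol),
    class = "fluct_calibration")
}

#' @export
print.fluct_calibration <- function(x, ...) {
  cat(sprintf("fluctuation calibration at f = %.3g pN (%d points)\n",
              x$force, x$n_points))
  cat(sprintf("  sigma_p = %.4f +/- %.4f\n", x$sigma_p, x$sigma_p_se))
  cat(sprintf("  kappa   = %.3f +/- %.3f nm^2 per nm of looped DNA\n",
              x$kappa, x$kappa_se))
  cat(sprintf("  |slope| = %.1f +/- %.1f nm/turn\n", x$slope_per_turn,
              x$slope_per_turn_se))
  invisible(x)
}

#' Infer the size of a topological domain from a variance drop
#'
#' The extension variance of supercoiled DNA drops by `kappa * delta_L` when
#' a loop of length `delta_L` is pinched off, so `delta_L = (var_before -
#' var_after) / kappa`, with the confidence interval propagated from both
#' variance standard errors and the calibration uncertainty.
#'
#' @param var_before,var_after Extension variances (nm^2) without/with the
#'   bridging protein.
#' @param calib A [calibrate_fluctuations()] result.
#' @param se_before,se_after Standard errors of the variances.
#' @param level Confidence level.
#' @return List: `delta_L` (nm), `se`, `ci`, `diagnostic` (`"ok"` or
#'   `"no_bridging"` when the variance did not drop).
#' @export
infer_domain_size <- function(var_before, var_after, calib,
                              se_before = 0, se_after = 0, level = 0.95) {
  stopifnot(inherits(calib, "fluct_calibration"))
  if (var_before < 0 || var_after < 0) stop("variances must be >= 0")
  if (calib$kappa <= 0) stop("calibration has non-positive kappa")
  drop <- var_before - var_after
  if (drop < 0) {
    return(list(delta_L = 0, se = NA_real_, ci = c(NA_real_, NA_real_),
                diagnostic = "no_bridging"))
  }
  dl <- drop / calib$kappa
  rel2 <- (se_before^2 + se_after^2) / max(drop^2, .Machine$double.eps) +
    (calib$kappa_se / calib$kappa)^2
  se <- dl * sqrt(rel2)
  q <- qnorm(1 - (1 - level) / 2)
  list(delta_L = dl, se = se, ci = c(max(0, dl - q * se), dl + q * se),
       diagnostic = "ok")
}

#' Change in mean extension between two traces
#'
#' Difference of pooled window means (after protein binding minus before),
#' with combined standard error and a test of the no-change null; the
#' two-phase model predicts no change in the mean upon loop formation.
#'
#' @param before,after [extension_trace()] objects at identical force and
#'   supercoiling density.
#' @param window_s Window length for pooling (s).
#' @return List: `delta_z` (nm), `se`, `z_score`, `p_value` for the
#'   no-change null.
#' @export
mean_extension_change <- function(before, after, window_s = 1.0) {
  stopifnot(inherits(before, "extension_trace"),
            inherits(after, "extension_trace"))
  same <- function(a, b) (is.na(a) && is.na(b)) ||
    (!is.na(a) && !is.na(b) && abs(a - b) <= 1e-9 * max(1, abs(a)))
  if (!same(before$force, after$force) || !same(before$sigma, after$sigma)) {
    stop("traces were recorded at different force or supercoiling density")
  }
  wb <- windowed_stats(before, window_s)
  wa <- windowed_stats(after, window_s)
  d <- wa$mean - wb$mean
  se <- sqrt(wa$mean_se^2 + wb$mean_se^2)
  zsc <- d / se
  list(delta_z = d, se = se, z_score = zsc,
       p_value = 2 * pnorm(-abs(zsc)))
}

#' Segment a trace into discrete extension states
#'
#' Smooths the raw trace with a sliding-window average, discovers discrete
#' extension levels as peaks of the density of the filtered signal
#' constrained to a common level spacing, and assigns every sample to the
#' nearest level with a hysteresis of 0.25 spacing. With fewer than two
#' resolvable peaks a single-state model is returned (a valid result, not an
#' error).
#'
#' @param trace An [extension_trace()], at least 10 filter windows long.
#' @param filter_window_s Sliding-average window (s).
#' @param min_peak_frac Peaks below this fraction of the tallest density
#'   peak are ignored.
#' @return Object of class `state_model`: `levels` (data.frame `ddlk`, `z`,
#'   `p`, `n_samples`), `spacing` +/- `spacing_se` (nm), `assignments`
#'   (level index per sample, NA at the filter edges), `filter_window_s`,
#'   `rate`.
#' @export
segment_states <- function(trace, filter_window_s = 10,
                           min_peak_frac = 0.05) {
  stopifnot(inherits(trace, "extension_trace"))
  w <- round(filter_window_s * trace$rate)
  n <- length(trace$z)
  if (n < 10 * w) stop("trace shorter than 10 filter windows")
  zf <- running_mean(trace$z, w)
  valid <- !is.na(zf)
  # level discovery on (a thinned version of) the filtered signal
  zv <- zf[valid]
  if (length(zv) > 2e5) zv <- zv[seq(1, length(zv), length.out = 2e5)]
  dens <- density(zv, n = 1024)
  pk <- local_maxima(dens$y)
  pk <- pk[dens$y[pk] >= min_peak_frac * max(dens$y[pk])]
  # prominence: a peak must rise clearly above the valley separating it from
  # its nearest taller peak (suppresses bumps on transition ramps)
  if (length(pk) > 1) {
    keep <- vapply(seq_along(pk), function(i) {
      taller <- pk[dens$y[pk] > dens$y[pk[i]]]
      if (!length(taller)) return(TRUE)
      nt <- taller[which.min(abs(taller - pk[i]))]
      valley <- min(dens$y[min(pk[i], nt):max(pk[i], nt)])
      valley < 0.6 * dens$y[pk[i]]
    }, logical(1))
    pk <- pk[keep]
  }
  centers <- dens$x[pk]
  heights <- dens$y[pk]
  if (length(centers) >= 2) {
    # common-spacing constraint: robust spacing from adjacent peak gaps,
    # then a weighted fit of center ~ ref + k * spacing
    gaps <- diff(centers)
    spacing <- stats::median(gaps)
    ref <- centers[which.max(heights)]
    k <- round((centers - ref) / spacing)
    if (anyDuplicated(k)) {
      keep <- !duplicated(k)
      centers <- centers[keep]; heights <- heights[keep]; k <- k[keep]
    }
    if (length(unique(k)) >= 2) {
      fit <- lm(centers ~ k, weights = heights)
      spacing <- unname(coef(fit)[2])
      spacing_se <- summary(fit)$coefficients[2, 2]
      levels_z <- unname(coef(fit)[1]) + spacing * k
    } else {
      spacing_se <- NA_real_
      levels_z <- centers
    }
  } else {
    spacing <- NA_real_
    spacing_se <- NA_real_
    levels_z <- centers
    k <- 0
  }
  margin <- if (is.na(spacing)) 0 else 0.25 * abs(spacing)
  assign <- cpp_hysteresis_assign(zf, levels_z, margin)
  counts <- tabulate(assign, nbins = length(levels_z))
  p <- counts / sum(counts)
  # states indexed by linking-number change relative to the most populated
  ddlk_sign <- -1  # extension decreases when the loop traps one more turn
  kk <- if (length(levels_z) >= 2) {
    ddlk_sign * round((levels_z - levels_z[which.max(p)]) / spacing)
  } else 0L
  structure(list(
    levels = data.frame(ddlk = kk, z = levels_z, p = p,
                        n_samples = counts),
    spacing = abs(spacing), spacing_se = spacing_se,
    assignments = assign, filter_window_s = filter_window_s,
    rate = trace$rate), class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("state model: %d level(s), spacing %.2f +/- %.2f nm\n",
              nrow(x$levels), x$spacing, x$spacing_se))
  print(x$levels, row.names = FALSE)
  invisible(x)
}

# centered sliding mean; NA over the first/last half windows
running_mean <- function(z, w) {
  n <- length(z)
  cs <- cumsum(c(0, z))
  out <- rep(NA_real_, n)
  starts <- 1:(n - w + 1)
  out[starts + w %/% 2] <- (cs[starts + w] - cs[starts]) / w
  out
}

local_maxima <- function(y) {
  n <- length(y)
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}

#' Plectoneme torsional stiffness from state occupancies
#'
#' The occupancies of the loop linking-number states are Gaussian with
#' variance `<ddlk^2> = delta_L / (4 pi^2 P)`; a weighted quadratic fit of
#' `log p` against the state index recovers that variance and hence the
#' effective torsional stiffness `P = delta_L / (4 pi^2 <ddlk^2>)` of the
#' plectonemic phase.
#'
#' @param state_model A [segment_states()] result (or any object with a
#'   `levels` data.frame holding `ddlk` and `p`), >= 3 occupied levels.
#' @param delta_L Looped DNA length (nm).
#' @return List: `P` (nm), `P_se`, `ddlk_var` (the fitted `<ddlk^2>`),
#'   `center` (fitted center of the Gaussian, turns).
#' @export
plectoneme_stiffness <- function(state_model, delta_L) {
  lv <- state_model$levels
  lv <- lv[lv$p > 0, ]
  if (nrow(lv) < 3) stop("need at least 3 occupied levels")
  fit <- lm(log(p) ~ ddlk + I(ddlk^2), data = lv, weights = lv$p)
  cc <- coef(fit)
  if (!is.finite(cc[3]) || cc[3] >= 0) {
    stop("occupancies are not Gaussian-decaying; cannot fit a stiffness")
  }
  v <- -1 / (2 * cc[3])
  center <- unname(cc[2]) * v
  se_c <- suppressWarnings(summary(fit))$coefficients[3, 2]
  v_se <- se_c / (2 * cc[3]^2)
  P <- delta_L / (4 * pi^2 * v)
  list(P = unname(P), P_se = unname(abs(P * v_se / v)),
       ddlk_var = unname(v), center = center)
}

#' Dwell times and loop kinetics from a segmented trace
#'
#' Extracts per-state dwell times from the state assignments (dropping the
#' censored first and last dwells, and dwells shorter than the filter window
#' which the sliding average cannot resolve), fits each state's dwell
#' distribution with a left-truncated exponential (`tau_i = mean(d) - w`, the
#' maximum-likelihood estimate), and converts to the intrinsic loop
#' dissociation/reformation time `tau_p = (1 - p_i) tau_i`. The summary
#' `tau_p` is the mean +/- SD over the most populated states.
#'
#' @param state_model A [segment_states()] result with `assignments`.
#' @param min_events Minimum usable dwells for a state to be analyzed.
#' @param n_top Number of most-populated states entering the summary.
#' @return Object of class `dwell_analysis`: `per_state` (data.frame
#'   `ddlk`, `p`, `n_dwells`, `n_short_excluded`, `tau_dwell`,
#'   `tau_dwell_se`, `tau_p`, `gof_p`), `tau_p`, `tau_p_sd`.
#' @export
dwell_time_analysis <- function(state_model, min_events = 20, n_top = 3) {
  a <- state_model$assignments
  a <- a[!is.na(a)]
  r <- rle(a)
  if (length(r$lengths) < 3) stop("fewer than 3 dwells in the trace")
  # drop censored first and last dwells
  keep <- 2:(length(r$lengths) - 1)
  durs <- r$lengths[keep] / state_model$rate
  states <- r$values[keep]
  w <- state_model$filter_window_s
  lv <- state_model$levels
  res <- lapply(seq_len(nrow(lv)), function(i) {
    d <- durs[states == i]
    short <- sum(d < w)
    d <- d[d >= w]
    if (length(d) < min_events) {
      return(data.frame(ddlk = lv$ddlk[i], p = lv$p[i], n_dwells = length(d),
                        n_short_excluded = short, tau_dwell = NA_real_,
                        tau_dwell_se = NA_real_, tau_p = NA_real_,
                        gof_p = NA_real_))
    }
    tau <- mean(d) - w  # left-truncated exponential MLE
    gof <- suppressWarnings(ks.test(d - w, "pexp", 1 / tau)$p.value)
    data.frame(ddlk = lv$ddlk[i], p = lv$p[i], n_dwells = length(d),
               n_short_excluded = short, tau_dwell = tau,
               tau_dwell_se = tau / sqrt(length(d)),
               tau_p = (1 - lv$p[i]) * tau, gof_p = gof)
  })
  per_state <- do.call(rbind, res)
  skipped <- sum(is.na(per_state$tau_dwell))
  if (skipped > 0) {
    warning(skipped, " state(s) skipped: fewer than ", min_events,
            " usable dwells")
  }
  ok <- per_state[!is.na(per_state$tau_p), ]
  ok <- ok[order(-ok$p), ]
  top <- utils::head(ok, n_top)
  structure(list(per_state = per_state,
                 tau_p = mean(top$tau_p), tau_p_sd = sd(top$tau_p),
                 n_states_used = nrow(top)), class = "dwell_analysis")
}

#' @export
print.dwell_analysis <- function(x, ...) {
  cat(sprintf("dwell-time analysis: tau_p = %.1f +/- %.1f s (%d states)\n",
              x$tau_p, x$tau_p_sd, x$n_states_used))
  print(x$per_state, row.names = FALSE, digits = 3)
  invisible(x)
}
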