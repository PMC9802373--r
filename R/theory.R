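#' @useDynLib plectofluct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef acf rnorm runif rexp sd var density optim
#'   qnorm pnorm ks.test setNames fft resid vcov quantile median dist
#' @importFrom utils write.table read.table head tail
NULL

# ---------------------------------------------------------------------------
# Stretched (prebuckling) phase: Moroz-Nelson high-force expansion.
#
# Free energy per unit length (pN), as a function of supercoiling density
# sigma at force f:
#   S(sigma, f) = -g(f) + (1/2) kBT cs(f) omega0^2 sigma^2
# with g(f) = f - sqrt(kBT f / A) the stretched-WLC free energy and
# cs(f) = C [1 - (C / 4A) sqrt(kBT / (A f))] the force-renormalized twist
# stiffness. The plectonemic phase is quadratic with a constant torsional
# stiffness P:  P(sigma) = (1/2) kBT P omega0^2 sigma^2, independent of force.
# ---------------------------------------------------------------------------

wlc_g <- function(f, params) f - sqrt(params$kBT * f / params$A)

wlc_g_prime <- function(f, params) 1 - 0.5 * sqrt(params$kBT / (params$A * f))

mn_cs <- function(f, params) {
  params$C * (1 - params$C / (4 * params$A) * sqrt(params$kBT / (params$A * f)))
}

mn_cs_prime <- function(f, params) {
  params$C^2 / (8 * params$A) * sqrt(params$kBT / params$A) * f^(-1.5)
}

#' Free energy per unit length of the stretched phase
#'
#' Moroz-Nelson model for stretched, twisted DNA below the buckling
#' transition: a stretched worm-like-chain term plus a quadratic twist term
#' with a force-renormalized effective twist stiffness. Even in `sigma`.
#'
#' @param sigma Supercoiling density (dimensionless), vectorized.
#' @param force Stretching force (pN), single positive value.
#' @param params An [elastic_params()] object.
#' @return Free energy per unit length (pN).
#' @export
stretched_free_energy <- function(sigma, force, params = elastic_params()) {
  params <- as_elastic_params(params)
  if (!is.numeric(force) || length(force) != 1L || !is.finite(force) ||
      force <= 0) {
    stop("'force' must be a single positive value (pN)")
  }
  cs <- mn_cs(force, params)
  -wlc_g(force, params) + 0.5 * params$kBT * cs * params$omega0^2 * sigma^2
}

#' Free energy per unit length of the plectonemic phase
#'
#' Quadratic in the supercoiling density with a constant effective torsional
#' stiffness `P`; independent of the applied force (the plectoneme does not
#' contribute to the extension).
#'
#' @inheritParams stretched_free_energy
#' @return Free energy per unit length (pN).
#' @export
plectoneme_free_energy <- function(sigma, params = elastic_params()) {
  params <- as_elastic_params(params)
  0.5 * params$kBT * params$P * params$omega0^2 * sigma^2
}

#' Two-phase coexistence by double-tangent construction
#'
#' Solves the common-tangent conditions between the stretched free energy
#' `S(sigma)` and the plectonemic free energy `P(sigma)`:
#' `S'(sigma_s) = P'(sigma_p) = (P(sigma_p) - S(sigma_s)) / (sigma_p -
#' sigma_s)`. For the quadratic forms used here the tangency conditions admit
#' a closed-form solution, which is returned directly (and verified against a
#' brute-force grid minimization in the test suite). The force-dependent
#' slope prefactor `Gamma` of the postbuckling extension and the
#' variance-per-looped-length factor `kappa = kBT * Gamma * d(sigma_p)/df`
#' are derived, the latter by Richardson-refined central differences in force.
#'
#' @param force Stretching force (pN).
#' @param params An [elastic_params()] object.
#' @return An object of class `phase_coexistence` with fields `sigma_s`,
#'   `sigma_p`, `Gamma`, `kappa` (nm), `dsigma_p_df` (1/pN), `force`,
#'   `params`.
#' @examples
#' cx <- solve_coexistence(0.5)
#' cx$sigma_p   # plectonemic supercoiling density at 0.5 pN
#' @export
solve_coexistence <- function(force, params = elastic_params()) {
  params <- as_elastic_params(params)
  if (!is.numeric(force) || length(force) != 1L || !is.finite(force) ||
      force <= 0) {
    stop("'force' must be a single positive value (pN)")
  }
  core <- coexistence_core(force, params)
  h <- 1e-3 * force
  dsig <- richardson_diff(function(f) coexistence_core(f, params)$sigma_p,
                          force, h)
  kappa <- params$kBT * core$Gamma * dsig
  obj <- c(core, list(dsigma_p_df = dsig, kappa = kappa,
                      force = force, params = params))
  class(obj) <- "phase_coexistence"
  obj
}

# closed-form tangency solution; requires g(f) > 0 and cs(f) > P
coexistence_core <- function(force, params) {
  g <- wlc_g(force, params)
  cs <- mn_cs(force, params)
  ct <- params$kBT * params$omega0^2 * cs  # stretched twist modulus, pN
  pt <- params$kBT * params$omega0^2 * params$P
  if (!is.finite(g) || g <= 0 || cs <= params$P) {
    stop("no stretched/plectonemic coexistence at force = ", force,
         " pN: the double-tangent construction is degenerate")
  }
  sigma_s <- sqrt(2 * g * pt / (1 - pt / ct)) / ct
  sigma_p <- ct * sigma_s / pt
  # extension fraction of the stretched phase at sigma_s (envelope theorem)
  z_s <- wlc_g_prime(force, params) -
    0.5 * params$kBT * params$omega0^2 * mn_cs_prime(force, params) * sigma_s^2
  list(sigma_s = sigma_s, sigma_p = sigma_p,
       Gamma = z_s / (sigma_p - sigma_s))
}

#' @export
print.phase_coexistence <- function(x, ...) {
  cat(sprintf("Two-phase coexistence at f = %.3g pN\n", x$force))
  cat(sprintf("  sigma_s = %.5f, sigma_p = %.5f\n", x$sigma_s, x$sigma_p))
  cat(sprintf("  Gamma   = %.3f (extension fraction per unit sigma)\n",
              x$Gamma))
  cat(sprintf("  kappa   = %.3f nm (variance drop per nm of looped DNA)\n",
              x$kappa))
  invisible(x)
}

# Richardson-refined central difference, step h then h/2
richardson_diff <- function(fun, x, h) {
  d1 <- (fun(x + h) - fun(x - h)) / (2 * h)
  d2 <- (fun(x + h / 2) - fun(x - h / 2)) / h
  (4 * d2 - d1) / 3
}

#' Equilibrium free energy per unit length of supercoiled DNA
#'
#' Below buckling (`sigma <= sigma_s`) the stretched-phase free energy;
#' in the coexistence window the double-tangent (linear-in-sigma) envelope.
#'
#' @inheritParams stretched_free_energy
#' @return Free energy per unit length (pN).
#' @export
supercoil_free_energy <- function(sigma, force, params = elastic_params()) {
  params <- as_elastic_params(params)
  cx <- coexistence_core(force, params)
  vapply(sigma, function(s) {
    s <- abs(s)  # model is even in sigma
    if (s <= cx$sigma_s) {
      stretched_free_energy(s, force, params)
    } else {
      nu <- (cx$sigma_p - s) / (cx$sigma_p - cx$sigma_s)
      nu * stretched_free_energy(cx$sigma_s, force, params) +
        (1 - nu) * plectoneme_free_energy(cx$sigma_p, params)
    }
  }, numeric(1))
}

#' Mean fractional extension of supercoiled DNA
#'
#' Prebuckling branch from the force derivative of the stretched free energy;
#' in the coexistence window the linear law `<z>/L = Gamma * (sigma_p -
#' sigma)`. The two branches are continuous at the buckling density
#' `sigma_s`. Overwinding only (`sigma >= 0`); densities beyond `sigma_p`
#' (fully plectonemic molecule) are refused.
#'
#' @inheritParams stretched_free_energy
#' @return Mean extension divided by contour length (dimensionless).
#' @export
mean_extension <- function(sigma, force, params = elastic_params()) {
  params <- as_elastic_params(params)
  if (any(sigma < 0)) {
    stop("sigma < 0 (underwound DNA) is outside the scope of this model")
  }
  cx <- coexistence_core(force, params)
  # a 1% margin keeps the linear branch usable by the centered force
  # derivatives right at the plectonemic boundary
  if (any(sigma > cx$sigma_p * 1.01 + 1e-12)) {
    stop(sprintf(
      "sigma beyond the fully plectonemic density sigma_p = %.5f is not modelled",
      cx$sigma_p))
  }
  csp <- mn_cs_prime(force, params)
  gp <- wlc_g_prime(force, params)
  vapply(sigma, function(s) {
    if (s <= cx$sigma_s) {
      gp - 0.5 * params$kBT * params$omega0^2 * csp * s^2
    } else {
      cx$Gamma * (cx$sigma_p - s)
    }
  }, numeric(1))
}

#' Extension variance per unit length of supercoiled DNA
#'
#' Computed from the fluctuation-response relation
#' `<dz^2>/L = kBT * d(<z>/L)/df` by Richardson-refined central differences
#' in the force (relative step 1e-3). On the coexistence branch the result
#' increases linearly with `sigma` and approaches `kappa` as `sigma ->
#' sigma_p`.
#'
#' @inheritParams stretched_free_energy
#' @return Extension variance divided by contour length (nm).
#' @export
extension_variance <- function(sigma, force, params = elastic_params()) {
  params <- as_elastic_params(params)
  h <- 1e-3 * force
  params$kBT * vapply(sigma, function(s) {
    richardson_diff(function(f) mean_extension(s, f, params), force, h)
  }, numeric(1))
}

#' Fit a power-law scaling exponent
#'
#' Least-squares slope of `log|value|` versus `log(force)`; used to verify
#' the large-force scaling laws of the prebuckling curvatures and
#' postbuckling slopes of the mean extension and extension variance.
#'
#' @param forces Strictly positive forces (pN), at least 4.
#' @param values Corresponding non-zero values.
#' @return Fitted exponent (dimensionless).
#' @examples
#' f <- c(1, 2, 4, 8)
#' fit_scaling_exponent(f, 3 * f^(-1.5))  # -1.5
#' @export
fit_scaling_exponent <- function(forces, values) {
  if (length(forces) < 4L || length(values) != length(forces)) {
    stop("need at least 4 force/value pairs of equal length")
  }
  if (any(!is.finite(forces)) || any(forces <= 0) ||
      any(!is.finite(values)) || any(values == 0)) {
    stop("forces must be positive and values non-zero and finite")
  }
  unname(coef(lm(log(abs(values)) ~ log(forces)))[2L])
}

#' Theoretical rotation curve
#'
#' Evaluates the two-phase model on a grid of supercoiling densities at one
#' force, in the units a magnetic-tweezers rotation curve is plotted in.
#'
#' @param sigma Grid of supercoiling densities (non-negative, increasing).
#' @param force Stretching force (pN).
#' @param molecule A [molecule_spec()].
#' @return A `rotation_curve` object (see [rotation_curve()]): columns
#'   `sigma`, `z` (nm), `var_z` (nm^2) plus zero standard errors.
#' @export
theory_rotation_curve <- function(sigma, force, molecule) {
  stopifnot(inherits(molecule, "molecule_spec"))
  params <- molecule$params
  z <- mean_extension(sigma, force, params) * molecule$L
  v <- extension_variance(sigma, force, params) * molecule$L
  rotation_curve(sigma = sigma, z = z, var_z = v,
                 se_z = rep(0, length(sigma)), se_var = rep(0, length(sigma)),
                 force = force, molecule = molecule)
}
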