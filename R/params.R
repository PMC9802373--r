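#' Elastic parameters of double-stranded DNA
#'
#' Container for the elastic constants and helical geometry that enter every
#' free energy in the package. The thermal energy `kBT` (pN nm) and the
#' intrinsic twist density `omega0 = 2*pi / (helical_repeat * helical_rise)`
#' (rad/nm) are derived fields, never stored independently.
#'
#' @param A Bending persistence length (nm).
#' @param C Twist persistence length (nm).
#' @param P Effective torsional stiffness of the plectonemic phase (nm).
#' @param helical_repeat Helical repeat (bp per turn).
#' @param helical_rise Helical rise (nm per bp).
#' @param temperature Absolute temperature (K).
#'
#' @return An object of class `elastic_params`.
#' @examples
#' p <- elastic_params()
#' p$kBT     # ~4.11 pN nm at 298 K
#' p$omega0  # ~1.76 rad/nm
#' @export
elastic_params <- function(A = 40, C = 100, P = 20,
                           helical_repeat = 10.5, helical_rise = 0.34,
                           temperature = 298) {
  vals <- c(A = A, C = C, P = P, helical_repeat = helical_repeat,
            helical_rise = helical_rise, temperature = temperature)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all elastic parameters must be finite and strictly positive")
  }
  kB <- 0.0138064852  # pN nm / K
  obj <- list(
    A = A, C = C, P = P,
    helical_repeat = helical_repeat, helical_rise = helical_rise,
    temperature = temperature,
    kBT = kB * temperature,
    omega0 = 2 * pi / (helical_repeat * helical_rise)
  )
  class(obj) <- "elastic_params"
  obj
}

#' @export
print.elastic_params <- function(x, ...) {
  cat("DNA elastic parameters\n")
  cat(sprintf("  bend persistence A:   %6.1f nm\n", x$A))
  cat(sprintf("  twist persistence C:  %6.1f nm\n", x$C))
  cat(sprintf("  plectoneme stiffness: %6.1f nm\n", x$P))
  cat(sprintf("  helical repeat:       %6.2f bp/turn\n", x$helical_repeat))
  cat(sprintf("  helical rise:         %6.3f nm/bp\n", x$helical_rise))
  cat(sprintf("  temperature:          %6.1f K  (kBT = %.4f pN nm)\n",
              x$temperature, x$kBT))
  cat(sprintf("  intrinsic twist w0:   %6.4f rad/nm\n", x$omega0))
  invisible(x)
}

as_elastic_params <- function(params) {
  if (inherits(params, "elastic_params")) return(params)
  stop("'params' must be created with elastic_params()")
}

#' DNA molecule specification
#'
#' Describes a torsionally constrained DNA tether by its length in base pairs.
#' The contour length `L = n_bp * helical_rise` (nm) and the relaxed linking
#' number `Lk0 = n_bp / helical_repeat` (turns) are derived from the helical
#' geometry in `params`.
#'
#' @param n_bp Number of base pairs (positive integer).
#' @param params An [elastic_params()] object supplying the helical geometry.
#' @return An object of class `molecule_spec` with fields `n_bp`, `L`, `Lk0`.
#' @examples
#' m <- molecule_spec(7900)
#' m$L    # 2686 nm
#' m$Lk0  # ~752 turns
#' @export
molecule_spec <- function(n_bp, params = elastic_params()) {
  params <- as_elastic_params(params)
  if (!is.numeric(n_bp) || length(n_bp) != 1L || !is.finite(n_bp) || n_bp < 1) {
    stop("'n_bp' must be a single positive number")
  }
  obj <- list(
    n_bp = n_bp,
    L = n_bp * params$helical_rise,
    Lk0 = n_bp / params$helical_repeat,
    params = params
  )
  class(obj) <- "molecule_spec"
  obj
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat(sprintf("DNA molecule: %d bp, L = %.1f nm, Lk0 = %.2f turns\n",
              round(x$n_bp), x$L, x$Lk0))
  invisible(x)
}

#' Convert between linking difference and supercoiling density
#'
#' The supercoiling density is `sigma = delta_lk / Lk0`, a length-independent
#' measure of over- or underwinding; `linking_difference()` is the inverse
#' operation.
#'
#' @param delta_lk Linking difference (turns), may be a vector.
#' @param sigma Supercoiling density (dimensionless), may be a vector.
#' @param molecule A [molecule_spec()].
#' @return Numeric vector: `sigma` resp. `delta_lk`.
#' @examples
#' m <- molecule_spec(2000)
#' linking_difference(0.06, m)  # ~11.4 turns
#' @export
supercoiling_density <- function(delta_lk, molecule) {
  stopifnot(inherits(molecule, "molecule_spec"))
  if (!is.finite(molecule$Lk0) || molecule$Lk0 <= 0) {
    stop("molecule has non-positive Lk0")
  }
  delta_lk / molecule$Lk0
}

#' @rdname supercoiling_density
#' @export
linking_difference <- function(sigma, molecule) {
  stopifnot(inherits(molecule, "molecule_spec"))
  if (!is.finite(molecule$Lk0) || molecule$Lk0 <= 0) {
    stop("molecule has non-positive Lk0")
  }
  sigma * molecule$Lk0
}
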