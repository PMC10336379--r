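#' Local exchange chemical potentials
#'
#' The local (gradient-free) part of the non-dimensional exchange
#' chemical potentials of the ternary Flory-Huggins mixture,
#' `mu_i = ln(phi_i) - ln(phi_S) + chi * phi_j`, where
#' `phi_S = 1 - phiA - phiI` is the solvent fraction and `j` is the
#' partner species.  The square-gradient contribution `-w^2 lap(phi_i)`
#' lives in [full_chemical_potentials()], which operates on discretized
#' fields.
#'
#' @param phiA,phiI Volume fractions (vectors/matrices of equal shape)
#'   strictly inside the composition simplex: `phiA > 0`, `phiI > 0`,
#'   `phiA + phiI < 1`.
#' @param params A [model_params()] object.
#' @return List with fields `mu_A` and `mu_I` (units `kB*T/nu`).
#' @export
local_chemical_potentials <- function(phiA, phiI, params) {
  validate_params(params)
  check_simplex(phiA, phiI)
  phiS <- 1 - phiA - phiI
  list(mu_A = log(phiA) - log(phiS) + params$chi * phiI,
       mu_I = log(phiI) - log(phiS) + params$chi * phiA)
}

check_simplex <- function(phiA, phiI, where = "fractions") {
  if (any(phiA <= 0) || any(phiI <= 0) || any(phiA + phiI >= 1)) {
    bad <- which(phiA <= 0 | phiI <= 0 | phiA + phiI >= 1)
    stop(where, " outside the open composition simplex ",
         "(phiA > 0, phiI > 0, phiA + phiI < 1); first offending index ",
         bad[1L], ": phiA = ", phiA[bad[1L]], ", phiI = ", phiI[bad[1L]],
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Flory-Huggins free energy density
#'
#' Integrand of the free energy functional: translational entropy of
#' activator, inhibitor and solvent, the `chi * phiA * phiI` interaction
#' term, and the square-gradient penalty `(w^2/2)(|grad phiA|^2 +
#' |grad phiI|^2)` that sets the interfacial width in strongly
#' interacting systems.
#'
#' @inheritParams local_chemical_potentials
#' @param gradsqA,gradsqI Squared gradient magnitudes of the two fields
#'   (non-negative; default 0 for uniform states).
#' @return Energy density in units of `kB*T/nu`.
#' @export
free_energy_density <- function(phiA, phiI, gradsqA = 0, gradsqI = 0,
                                params) {
  validate_params(params)
  check_simplex(phiA, phiI)
  if (any(gradsqA < 0) || any(gradsqI < 0))
    stop("squared-gradient arguments must be non-negative", call. = FALSE)
  phiS <- 1 - phiA - phiI
  phiA * log(phiA) + phiI * log(phiI) + phiS * log(phiS) +
    params$chi * phiA * phiI +
    (params$w^2 / 2) * (gradsqA + gradsqI)
}

#' Hessian of the local free energy
#'
#' Matrix of derivatives `d mu_i / d phi_j` of the local exchange
#' chemical potentials:
#' diagonal `1/phi_i + 1/phi_S`, off-diagonal `1/phi_S + chi`.  It is
#' symmetric, and positive definite exactly when the local mixture is
#' thermodynamically stable.  Its eigenvector `(1, -1)` (segregative
#' direction, A against I) has eigenvalue `1/phi_i - chi` at the
#' symmetric point `phiA = phiI`, which vanishes at the segregative
#' spinodal [chi_plus()]; the `(1, 1)` direction (associative, A and I
#' against solvent) has eigenvalue `1/phi_i + 2/phi_S + chi` there.
#'
#' @inheritParams local_chemical_potentials
#' @return A 2x2 symmetric numeric matrix.
#' @export
local_hessian <- function(phiA, phiI, params) {
  validate_params(params)
  if (length(phiA) != 1L || length(phiI) != 1L)
    stop("local_hessian expects scalar fractions", call. = FALSE)
  check_simplex(phiA, phiI)
  phiS <- 1 - phiA - phiI
  off <- 1 / phiS + params$chi
  matrix(c(1 / phiA + 1 / phiS, off,
           off, 1 / phiI + 1 / phiS), nrow = 2)
}

#' Segregative spinodal threshold
#'
#' Interaction strength above which the homogeneous mixture is locally
#' unstable against segregation of A from I: `chi_plus = 1/phi0`, the
#' root of the `(1, -1)` eigenvalue of [local_hessian()] at the
#' homogeneous state.  Beyond it A separates from I spontaneously, even
#' without reactions.
#'
#' @param phi0 Mean fraction of each species, in `(0, 1/2)`.
#' @return The threshold Flory parameter (dimensionless).
#' @export
chi_plus <- function(phi0) {
  check_phi0(phi0)
  1 / phi0
}

#' Associative binodal threshold
#'
#' Interaction strength below which a phase enriched in both A and I can
#' coexist with a solvent-rich phase (associative demixing under strong
#' mutual attraction):
#' `chi_minus = 8 * atanh(1 - 4*phi0) / (4*phi0 - 1)`,
#' continuously extended to its limit value `-8` at `phi0 = 1/4`.
#' For `phi0 < 1/4` the value is negative, and it is always less
#' negative than the associative spinodal `-(1/phi0 + 2/(1 - 2*phi0))`.
#'
#' @inheritParams chi_plus
#' @return The threshold Flory parameter (dimensionless, negative for
#'   `phi0 < 1/4`).
#' @export
chi_minus <- function(phi0) {
  check_phi0(phi0)
  y <- 1 - 4 * phi0
  # atanh(y)/y -> 1 as y -> 0; switch to the series value near the
  # removable singularity at phi0 = 1/4
  ifelse(abs(y) < 1e-8, -8, -8 * atanh(y) / y)
}

check_phi0 <- function(phi0) {
  if (any(!is.finite(phi0)) || any(phi0 <= 0) || any(phi0 >= 0.5))
    stop("phi0 must lie in (0, 1/2)", call. = FALSE)
  invisible(phi0)
}
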