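#' Hill-Langmuir reaction rates
#'
#' Net production rates of activator and inhibitor,
#' `R_i = k * (2*phi0 / (1 + (phiI/phiA)^h) - phi_i)`: a shared
#' production term switched by the inhibitor-to-activator ratio, plus
#' linear degradation of each species at rate `k`.  Both rates vanish
#' at the homogeneous state `phiA = phiI = phi0` because the ratio is 1.
#'
#' The ratio power is evaluated as `exp(h * (log(phiI) - log(phiA)))`
#' so extreme ratios underflow or overflow gracefully; the production
#' term is clamped to `[0, 2*phi0]`.
#'
#' @param phiA,phiI Volume fractions (vectors or matrices of equal
#'   shape).  `phiA` must be strictly positive so the ratio is defined;
#'   `phiI` may be zero.
#' @param params A [model_params()] object.
#' @return A list with fields `R_A` and `R_I`, same shape as the inputs,
#'   in units of `D_A/w^2` per unit fraction.
#' @export
reaction_rates <- function(phiA, phiI, params) {
  validate_params(params)
  if (any(phiA <= 0)) {
    bad <- which(phiA <= 0)
    stop("reaction_rates: phiA must be strictly positive; first offending ",
         "location: index ", bad[1L], " (value ", phiA[bad[1L]], ")",
         call. = FALSE)
  }
  if (any(phiI < 0))
    stop("reaction_rates: phiI must be non-negative", call. = FALSE)
  ratio_pow <- exp(params$h * (log(phiI) - log(phiA)))
  production <- 2 * params$phi0 / (1 + ratio_pow)
  production <- pmin(pmax(production, 0), 2 * params$phi0)
  list(R_A = params$k * (production - phiA),
       R_I = params$k * (production - phiI))
}

#' Jacobian of the reaction term at the homogeneous state
#'
#' Derivatives of the Hill-Langmuir rates with respect to `(phiA, phiI)`
#' evaluated at `phiA = phiI = phi0`.  The closed form is
#' \deqn{R' = k \begin{pmatrix} h/2 - 1 & -h/2 \\ h/2 & -h/2 - 1
#' \end{pmatrix},}
#' with trace `-2k` and determinant `k^2`, so both eigenvalues equal
#' `-k` (a defective double root): spatially uniform perturbations
#' always decay at the degradation rate.
#'
#' @param params A [model_params()] object.
#' @return A 2x2 numeric matrix, rows/columns ordered (A, I).
#' @export
reaction_jacobian <- function(params) {
  validate_params(params)
  h <- params$h
  k <- params$k
  k * matrix(c(h / 2 - 1, h / 2,
               -h / 2,    -h / 2 - 1), nrow = 2)
}
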