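#' Default wavenumber grid for dispersion relations
#'
#' 1024 logarithmically spaced wavenumbers on `[2*pi/L_ref, pi/w]` with
#' `L_ref = 2000*w` (the largest box used in replication runs), covering
#' both the long reaction-diffusion scales and the interfacial scale.
#'
#' @param w Interfacial width parameter (length unit).
#' @param L_ref Largest wavelength of interest (box size).
#' @param n Number of grid points.
#' @return Strictly increasing numeric vector of wavenumbers (`q > 0`).
#' @export
default_q_grid <- function(w = 1, L_ref = 2000 * w, n = 1024) {
  exp(seq(log(2 * pi / L_ref), log(pi / w), length.out = n))
}

#' Dynamical matrix of the linearized dynamics
#'
#' Linearizing the non-ideal dynamics about the homogeneous state for a
#' perturbation with wavenumber `q` gives
#' `J(q) = -q^2 * M %*% (H + w^2 q^2 I) + R`, where
#' `M = diag(D_A*phi0, D_I*phi0)` are the mobilities, `H` the
#' [local_hessian()] at the homogeneous state, and `R` the
#' [reaction_jacobian()].  At `q = 0` it reduces to `R` (eigenvalues
#' both `-k`); for large `q` the quartic interfacial term dominates and
#' all modes decay.
#'
#' @param params A [model_params()] object.
#' @param q A single non-negative wavenumber (units `1/w`).
#' @return A 2x2 numeric matrix (units `D_A/w^2`).
#' @export
dynamical_matrix <- function(params, q) {
  validate_params(params)
  if (length(q) != 1L || q < 0) stop("q must be a single value >= 0",
                                     call. = FALSE)
  H <- local_hessian(params$phi0, params$phi0, params)
  R <- reaction_jacobian(params)
  M <- diag(c(params$D_A, params$D_I) * params$phi0)
  -q^2 * (M %*% (H + params$w^2 * q^2 * diag(2))) + R
}

# Largest real part of the eigenvalues of J(q), vectorized over q using
# the closed-form 2x2 trace/determinant formula (exact and fast for
# parameter sweeps).
sigma_max_of_q <- function(params, q) {
  phi0 <- params$phi0
  phiS <- 1 - 2 * phi0
  Hd <- 1 / phi0 + 1 / phiS
  Ho <- 1 / phiS + params$chi
  R <- reaction_jacobian(params)
  mA <- params$D_A * phi0
  mI <- params$D_I * phi0
  q2 <- q^2
  g <- params$w^2 * q2            # interfacial stiffening, adds to diagonal
  J11 <- -q2 * mA * (Hd + g) + R[1, 1]
  J12 <- -q2 * mA * Ho + R[1, 2]
  J21 <- -q2 * mI * Ho + R[2, 1]
  J22 <- -q2 * mI * (Hd + g) + R[2, 2]
  tr <- J11 + J22
  det <- J11 * J22 - J12 * J21
  disc <- tr^2 / 4 - det
  # guard against catastrophic cancellation at (near-)defective points
  # (e.g. q = 0, where both eigenvalues are exactly -k): treat a
  # discriminant at roundoff scale as a double root
  scale <- tr^2 / 4 + abs(det)
  disc[disc < 1e-14 * scale] <- 0
  sig <- tr / 2
  real <- disc > 0
  sig[real] <- sig[real] + sqrt(disc[real])
  sig
}

#' Dispersion relation of the homogeneous state
#'
#' Evaluates the largest eigenvalue growth rate `sigma_max(q)` of the
#' linearized dynamics on a grid of wavenumbers and locates the fastest
#' growing mode.  The state is flagged unstable when any `q > 0` mode
#' grows faster than the tolerance `1e-10 * D_A/w^2` (separating
#' marginal modes from roundoff).  Ties in the argmax resolve to the
#' smallest wavenumber for determinism.
#'
#' @param params A [model_params()] object.
#' @param q_grid Strictly increasing non-negative wavenumbers; `q = 0`
#'   is prepended as a reference if absent.
#' @param tol Instability tolerance on the growth rate.
#' @return An object of class `dispersion_curve`: list with fields `q`,
#'   `sigma_max`, `q_star`, `sigma_star`, `unstable`, `tol`.
#' @export
dispersion_relation <- function(params, q_grid = default_q_grid(params$w),
                                tol = 1e-10 * params$D_A / params$w^2) {
  validate_params(params)
  if (length(q_grid) == 0L || any(q_grid < 0))
    stop("q_grid must be non-empty and non-negative", call. = FALSE)
  q_grid <- sort(unique(as.numeric(q_grid)))
  if (q_grid[1L] > 0) q_grid <- c(0, q_grid)
  sig <- sigma_max_of_q(params, q_grid)
  pos <- which(q_grid > 0)
  i_star <- pos[which.max(sig[pos])]   # which.max: first index wins ties
  structure(list(q = q_grid, sigma_max = sig,
                 q_star = q_grid[i_star], sigma_star = sig[i_star],
                 unstable = sig[i_star] > tol, tol = tol),
            class = "dispersion_curve")
}

#' @export
print.dispersion_curve <- function(x, ...) {
  cat(sprintf(
    "Dispersion curve: %d wavenumbers on [%.3g, %.3g]\n  %s; q* = %.5g, sigma* = %.5g\n",
    length(x$q), min(x$q), max(x$q),
    if (x$unstable) "UNSTABLE" else "stable", x$q_star, x$sigma_star))
  invisible(x)
}

#' @export
as.data.frame.dispersion_curve <- function(x, ...) {
  data.frame(q = x$q, sigma_max = x$sigma_max)
}

#' Write a dispersion curve to CSV
#'
#' Two columns `q, sigma_max` with a header row.
#'
#' @param curve A [dispersion_relation()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dispersion_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Effective diffusivity matrix of the weak-interaction expansion
#'
#' To first order in `chi` (and for pattern wavelengths large compared
#' with `w`) the non-ideal transport reduces to ideal diffusion with the
#' matrix
#' \deqn{D = \begin{pmatrix} D_A(1+\psi) & D_A(\psi + \chi\phi_0) \\
#'   D_I(\psi + \chi\phi_0) & D_I(1+\psi) \end{pmatrix},
#'   \quad \psi = \frac{\phi_0}{1 - 2\phi_0}.}
#' Interactions enter only through the off-diagonal cross-diffusion
#' entries; repulsion (`chi > 0`) drives A down gradients of I and vice
#' versa.  Algebraically the matrix is exactly
#' `diag(D_A*phi0, D_I*phi0) %*% local_hessian(phi0, phi0)`.
#'
#' @param params A [model_params()] object.
#' @return A 2x2 numeric matrix (units of `D_A`).
#' @export
effective_diffusivity_matrix <- function(params) {
  validate_params(params)
  psi <- params$phi0 / (1 - 2 * params$phi0)
  cross <- psi + params$chi * params$phi0
  matrix(c(params$D_A * (1 + psi), params$D_I * cross,
           params$D_A * cross,     params$D_I * (1 + psi)), nrow = 2)
}

#' Minimal interaction strength supporting patterns
#'
#' The smallest Flory parameter `chi*` at which the homogeneous state
#' loses linear stability as `chi` increases: below `chi*` (but above
#' any attraction-driven instability) the system stays homogeneous;
#' above it, patterns grow.  Found numerically: a pre-scan over equally
#' spaced `chi` values locates the last stable-to-unstable transition in
#' the bracket, then bisection refines the boundary below `tol`.
#'
#' `chi* = 0` parameters form Turing patterns without any interaction;
#' `chi* > chi_plus(phi0)` parameters require segregative phase
#' separation to pattern.
#'
#' @param params A [model_params()] object; its `chi` field is ignored
#'   and swept instead.
#' @param bracket Interval of `chi` to search (default `c(-15, 10)`
#'   spans all regimes of interest).
#' @param tol Bisection tolerance on `chi` (default `1e-4`).
#' @param prescan_n Number of equally spaced pre-scan points.
#' @param q_grid Wavenumber grid passed to [dispersion_relation()].
#' @return The threshold `chi*` (scalar).
#' @export
chi_star <- function(params, bracket = c(-15, 10), tol = 1e-4,
                     prescan_n = 26, q_grid = default_q_grid(params$w)) {
  validate_params(params)
  if (length(bracket) != 2L || bracket[1] >= bracket[2])
    stop("bracket must be an increasing interval", call. = FALSE)
  unstable_at <- function(chi)
    dispersion_relation(update_params(params, chi = chi),
                        q_grid = q_grid)$unstable
  chis <- seq(bracket[1], bracket[2], length.out = prescan_n)
  flags <- vapply(chis, unstable_at, logical(1))
  # last stable -> unstable transition going up in chi
  trans <- which(!flags[-length(flags)] & flags[-1])
  if (length(trans) == 0L) {
    d_lo <- dispersion_relation(update_params(params, chi = bracket[1]),
                                q_grid = q_grid)
    d_hi <- dispersion_relation(update_params(params, chi = bracket[2]),
                                q_grid = q_grid)
    stop(sprintf(paste0(
      "chi_star: no stable-to-unstable transition in [%g, %g]; ",
      "dispersion extrema sigma* = %.4g (chi = %g), %.4g (chi = %g)"),
      bracket[1], bracket[2], d_lo$sigma_star, bracket[1],
      d_hi$sigma_star, bracket[2]), call. = FALSE)
  }
  i <- trans[length(trans)]
  lo <- chis[i]       # stable
  hi <- chis[i + 1]   # unstable
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (unstable_at(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Stability boundaries in the chi direction along a parameter axis
#'
#' For each value of the swept axis, scans `chi` over `chi_range` and
#' refines every flip of the instability verdict by bisection; between
#' consecutive boundary values the verdict is constant on the scan grid.
#' These are the boundaries of the stable homogeneous region in
#' parameter-plane diagrams (typically a lower, attraction-driven
#' boundary and an upper, repulsion/Turing-driven one).
#'
#' @param base A [model_params()] object giving all non-swept values.
#' @param axis One of `"h"`, `"D_I/D_A"`, `"k"`.
#' @param range Interval `c(lo, hi)` for the axis.
#' @param resolution Number of axis values (>= 2).
#' @param chi_range Interval of `chi` scanned at each axis value.
#' @param n_chi Number of chi scan points per axis value.
#' @param tol Bisection tolerance on each boundary.
#' @return A list with one element per axis value: list(axis_value,
#'   boundaries) where `boundaries` is a (possibly empty) numeric
#'   vector of chi values at which the verdict flips.  Bracketing
#'   failures at individual points produce a warning and a missing
#'   entry.  Also carries attribute `axis`.
#' @export
stability_boundary <- function(base, axis, range, resolution,
                               chi_range = c(-15, 10), n_chi = 61,
                               tol = 1e-4) {
  validate_params(base)
  if (!axis %in% c("h", "D_I/D_A", "k"))
    stop('axis must be one of "h", "D_I/D_A", "k"', call. = FALSE)
  if (resolution < 2) stop("resolution must be >= 2", call. = FALSE)
  vals <- seq(range[1], range[2], length.out = resolution)
  set_axis <- function(v) {
    if (axis == "h") update_params(base, h = v)
    else if (axis == "k") update_params(base, k = v)
    else update_params(base, D_I = v * base$D_A)
  }
  out <- lapply(vals, function(v) {
    p <- set_axis(v)
    res <- tryCatch({
      chis <- seq(chi_range[1], chi_range[2], length.out = n_chi)
      flags <- vapply(chis, function(chi)
        dispersion_relation(update_params(p, chi = chi))$unstable,
        logical(1))
      flips <- which(flags[-length(flags)] != flags[-1])
      vapply(flips, function(i) {
        lo <- chis[i]; hi <- chis[i + 1]
        f_lo <- flags[i]
        while (hi - lo > tol) {
          mid <- (lo + hi) / 2
          f_mid <- dispersion_relation(
            update_params(p, chi = mid))$unstable
          if (f_mid == f_lo) lo <- mid else hi <- mid
        }
        (lo + hi) / 2
      }, numeric(1))
    }, error = function(e) {
      warning("stability_boundary failed at ", axis, " = ", v, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    list(axis_value = v, boundaries = res)
  })
  attr(out, "axis") <- axis
  out
}

#' Write stability boundaries to CSV
#'
#' One row per axis value with columns `axis, chi_boundary_1, ...`
#' (ragged rows padded with `NA`).
#'
#' @param bounds Result of [stability_boundary()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_boundary_csv <- function(bounds, path) {
  nb <- max(c(1L, vapply(bounds, function(b) length(b$boundaries),
                         integer(1))))
  rows <- lapply(bounds, function(b) {
    v <- rep(NA_real_, nb)
    if (length(b$boundaries)) v[seq_along(b$boundaries)] <- b$boundaries
    c(b$axis_value, v)
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("axis", paste0("chi_boundary_", seq_len(nb)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pattern length scale predicted by linear stability analysis
#'
#' Wavelength of the fastest-growing mode, `2*pi/q_star`.  For weak
#' interactions it tracks the reaction-diffusion length `sqrt(D/k)`
#' (hence scales as `k^(-1/2)`); for strong interactions the initial
#' instability is interfacial and the length is of order `w`.
#'
#' @param params A [model_params()] object (must be linearly unstable).
#' @param q_grid Wavenumber grid.
#' @return Length in units of `w`.
#' @export
lsa_length_scale <- function(params, q_grid = default_q_grid(params$w)) {
  d <- dispersion_relation(params, q_grid = q_grid)
  if (!d$unstable)
    stop("lsa_length_scale: parameters are linearly stable, no growing mode",
         call. = FALSE)
  2 * pi / d$q_star
}
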