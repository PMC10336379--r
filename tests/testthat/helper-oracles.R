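# Independent numerical oracles, deliberately built on different
# algorithms than the package code paths they check.

# --- Common-tangent (Maxwell) construction for the associative binodal.
#
# Along the symmetric direction phiA = phiI = phi/2 the local free
# energy reduces to the single-field form
#   f(phi) = phi*log(phi/2) + (1 - phi)*log(1 - phi) + chi*phi^2/4 .
# Coexisting compositions (phi_a, phi_b) satisfy equal chemical
# potential f'(phi_a) = f'(phi_b) and equal grand potential
# f - phi*f'.  We find them by a nested root search: for a trial common
# potential mu the outer roots of f'(phi) = mu are located on the two
# increasing branches (outside the spinodal interval), then mu is tuned
# until the grand potentials match.
binodal_pair_oracle <- function(chi) {
  stopifnot(chi < -8)            # double-well regime of this free energy
  fp <- function(phi) log(phi / (2 * (1 - phi))) + chi * phi / 2
  omega <- function(phi) {
    f <- phi * log(phi / 2) + (1 - phi) * log(1 - phi) + chi * phi^2 / 4
    f - phi * fp(phi)
  }
  # spinodal points: f''(phi) = 1/phi + 1/(1-phi) + chi/2 = 0
  fpp <- function(phi) 1 / phi + 1 / (1 - phi) + chi / 2
  s1 <- stats::uniroot(fpp, c(1e-12, 0.5), tol = 1e-14)$root
  s2 <- stats::uniroot(fpp, c(0.5, 1 - 1e-12), tol = 1e-14)$root
  lo_branch <- function(mu)
    stats::uniroot(function(p) fp(p) - mu, c(1e-14, s1), tol = 1e-15)$root
  hi_branch <- function(mu)
    stats::uniroot(function(p) fp(p) - mu, c(s2, 1 - 1e-14),
                   tol = 1e-15)$root
  gap <- function(mu) omega(lo_branch(mu)) - omega(hi_branch(mu))
  eps <- 1e-9 * (fp(s1) - fp(s2))
  mu_star <- stats::uniroot(gap, c(fp(s2) + eps, fp(s1) - eps),
                            tol = 1e-14)$root
  c(lo = lo_branch(mu_star), hi = hi_branch(mu_star))
}

# chi at which the dilute binodal branch passes through phi = 2*phi0
chi_minus_oracle <- function(phi0) {
  stopifnot(phi0 > 0, phi0 < 0.25)
  stats::uniroot(function(chi) binodal_pair_oracle(chi)[["lo"]] - 2 * phi0,
                 c(-40, -8 - 1e-6), tol = 1e-12)$root
}

# --- Pure-R reference for the discrete operators (periodic shifts).
shift1 <- function(x, by) {
  n <- length(x)
  x[((seq_len(n) - 1 - by) %% n) + 1]
}

# full exchange chemical potentials, 1D reference
ref_mu_1d <- function(phiA, phiI, dx, params) {
  phiS <- 1 - phiA - phiI
  lap <- function(f) (shift1(f, 1) + shift1(f, -1) - 2 * f) / dx^2
  list(mu_A = log(phiA) - log(phiS) + params$chi * phiI -
         params$w^2 * lap(phiA),
       mu_I = log(phiI) - log(phiS) + params$chi * phiA -
         params$w^2 * lap(phiI))
}

# staggered-grid conservative divergence, 1D reference
ref_div_1d <- function(phi, mu, dx, D) {
  f_right <- 0.5 * D * (phi + shift1(phi, 1)) * (shift1(mu, 1) - mu) / dx
  (f_right - shift1(f_right, -1)) / dx
}

shift2 <- function(m, by_row, by_col) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - by_row) %% nr) + 1,
    ((seq_len(nc) - 1 - by_col) %% nc) + 1, drop = FALSE]
}

ref_mu_2d <- function(phiA, phiI, dx, params) {
  phiS <- 1 - phiA - phiI
  lap <- function(f)
    (shift2(f, 1, 0) + shift2(f, -1, 0) + shift2(f, 0, 1) +
       shift2(f, 0, -1) - 4 * f) / dx^2
  list(mu_A = log(phiA) - log(phiS) + params$chi * phiI -
         params$w^2 * lap(phiA),
       mu_I = log(phiI) - log(phiS) + params$chi * phiA -
         params$w^2 * lap(phiI))
}

ref_div_2d <- function(phi, mu, dx, D) {
  fx <- 0.5 * D * (phi + shift2(phi, 1, 0)) * (shift2(mu, 1, 0) - mu) / dx
  fy <- 0.5 * D * (phi + shift2(phi, 0, 1)) * (shift2(mu, 0, 1) - mu) / dx
  (fx - shift2(fx, -1, 0)) / dx + (fy - shift2(fy, 0, -1)) / dx
}
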