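test_that("parameter validation enforces the model invariants", {
  expect_s3_class(model_params(), "model_params")
  expect_error(model_params(phi0 = 0.5), "phi0")
  expect_error(model_params(phi0 = 0), "phi0")
  expect_error(model_params(h = 0.5), "Hill")
  expect_error(model_params(k = -1), "k must")
  expect_error(model_params(D_I = 0), "D_I")
  expect_error(model_params(w = -1), "w must")
  expect_error(update_params(model_params(), bogus = 1), "unknown")
})

test_that("parameters round-trip through flat JSON; unknown keys rejected", {
  p <- model_params(phi0 = 0.2, chi = -3.5, h = 5, k = 0.1, D_I = 10)
  q <- params_from_json(params_to_json(p))
  expect_equal(unclass(q), unclass(p))
  f <- withr::local_tempfile(fileext = ".json")
  params_to_json(p, f)
  expect_equal(unclass(params_from_json(f)), unclass(p))
  expect_error(params_from_json('{"phi0": 0.2, "gamma": 1}'), "unknown")
})

test_that("homogeneous state is a reaction fixed point for any valid params", {
  for (phi0 in c(0.05, 0.2, 0.4)) {
    for (h in c(1, 2, 5, 10)) {
      p <- model_params(phi0 = phi0, h = h, k = 0.1)
      hs <- homogeneous_state(p)
      expect_equal(unname(hs), c(phi0, phi0))
      r <- reaction_rates(hs[1], hs[2], p)
      expect_equal(unname(r$R_A), 0)
      expect_equal(unname(r$R_I), 0)
    }
  }
})

test_that("reaction rates match direct Hill-Langmuir arithmetic", {
  p <- model_params(phi0 = 0.2, h = 5, k = 0.1)
  # production = 2*0.2 / (1 + (0.15/0.25)^5), independent arithmetic
  prod <- 0.4 / (1 + 0.6^5)
  r <- reaction_rates(0.25, 0.15, p)
  expect_equal(r$R_A, 0.1 * (prod - 0.25), tolerance = 1e-14)
  expect_equal(r$R_I, 0.1 * (prod - 0.15), tolerance = 1e-14)
  # saturated Hill function: production -> 0, pure degradation
  r2 <- reaction_rates(1e-9, 0.3, p)
  expect_equal(r2$R_A, -0.1 * 1e-9, tolerance = 1e-12)
  expect_equal(r2$R_I, -0.1 * 0.3, tolerance = 1e-12)
  # perturbed state near the fixed point reacts
  r3 <- reaction_rates(0.21, 0.2, p)
  expect_gt(abs(r3$R_A), 0)
  expect_error(reaction_rates(-0.1, 0.2, p), "offending")
  expect_error(reaction_rates(0, 0.2, p), "positive")
})

test_that("reaction Jacobian has the closed form and matches finite differences", {
  expect_equal(reaction_jacobian(model_params(h = 5, k = 0.1)),
               matrix(c(0.15, 0.25, -0.25, -0.35), 2))
  expect_equal(reaction_jacobian(model_params(h = 2, k = 0.3))[1, 1], 0)
  eps <- 1e-6
  for (h in c(1, 2, 5, 10)) {
    for (k in c(0.01, 0.1, 1)) {
      p <- model_params(phi0 = 0.2, h = h, k = k)
      J <- reaction_jacobian(p)
      fd <- matrix(0, 2, 2)
      base <- c(0.2, 0.2)
      for (j in 1:2) {
        up <- base; up[j] <- up[j] + eps
        dn <- base; dn[j] <- dn[j] - eps
        ru <- reaction_rates(up[1], up[2], p)
        rd <- reaction_rates(dn[1], dn[2], p)
        fd[, j] <- (c(ru$R_A, ru$R_I) - c(rd$R_A, rd$R_I)) / (2 * eps)
      }
      expect_equal(J, fd, tolerance = 1e-6)
      # double eigenvalue -k: trace -2k, determinant k^2
      expect_equal(sum(diag(J)), -2 * k, tolerance = 1e-12)
      expect_equal(det(J), k^2, tolerance = 1e-12)
    }
  }
})

test_that("local chemical potentials: closed-form values and A/I symmetry", {
  p0 <- model_params(phi0 = 0.2, chi = 0)
  mu <- local_chemical_potentials(0.2, 0.2, p0)
  expect_equal(mu$mu_A, log(1 / 3), tolerance = 1e-12)
  expect_equal(mu$mu_I, log(1 / 3), tolerance = 1e-12)
  p5 <- update_params(p0, chi = 5)
  expect_equal(local_chemical_potentials(0.2, 0.2, p5)$mu_A,
               log(1 / 3) + 1, tolerance = 1e-12)
  expect_equal(local_chemical_potentials(1 / 3, 1 / 3, p0)$mu_A, 0,
               tolerance = 1e-12)
  # swapping the fields swaps the outputs
  m1 <- local_chemical_potentials(0.3, 0.1, p5)
  m2 <- local_chemical_potentials(0.1, 0.3, p5)
  expect_equal(m1$mu_A, m2$mu_I)
  expect_equal(m1$mu_I, m2$mu_A)
  expect_error(local_chemical_potentials(0.7, 0.4, p0), "simplex")
  expect_error(local_chemical_potentials(-0.1, 0.2, p0), "simplex")
})

test_that("free energy density: entropy + interaction + gradient terms", {
  p <- model_params(phi0 = 0.2, chi = 0)
  f0 <- 0.4 * log(0.2) + 0.6 * log(0.6)
  expect_equal(free_energy_density(0.2, 0.2, params = p), f0,
               tolerance = 1e-12)
  p11 <- update_params(p, chi = -11)
  expect_equal(free_energy_density(0.2, 0.2, params = p11),
               f0 - 11 * 0.04, tolerance = 1e-12)
  expect_equal(free_energy_density(0.2, 0.2, 1, 1, p) -
                 free_energy_density(0.2, 0.2, 0, 0, p), 1.0)
  # invariance under A <-> I exchange for uniform states
  expect_equal(free_energy_density(0.3, 0.1, params = p11),
               free_energy_density(0.1, 0.3, params = p11))
  expect_error(free_energy_density(0.2, 0.2, -1, 0, p), "non-negative")
})

test_that("local Hessian: closed form, symmetry, finite-difference check", {
  p <- model_params(phi0 = 0.2, chi = 0)
  H <- local_hessian(0.2, 0.2, p)
  expect_equal(H, matrix(c(1 / 0.2 + 1 / 0.6, 1 / 0.6,
                           1 / 0.6, 1 / 0.2 + 1 / 0.6), 2),
               tolerance = 1e-12)
  set.seed(11)
  eps <- 1e-7
  for (i in 1:100) {
    pt <- random_simplex_point()
    pr <- update_params(p, chi = stats::runif(1, -10, 8))
    H <- local_hessian(pt[1], pt[2], pr)
    expect_identical(H[1, 2], H[2, 1])
    fd <- matrix(0, 2, 2)
    for (j in 1:2) {
      up <- pt; up[j] <- up[j] + eps
      dn <- pt; dn[j] <- dn[j] - eps
      mu_u <- local_chemical_potentials(up[1], up[2], pr)
      mu_d <- local_chemical_potentials(dn[1], dn[2], pr)
      fd[, j] <- (c(mu_u$mu_A, mu_u$mu_I) - c(mu_d$mu_A, mu_d$mu_I)) /
        (2 * eps)
    }
    expect_equal(H, fd, tolerance = 1e-5)
  }
})

test_that("Hessian eigen-directions encode the two demixing modes", {
  phi0 <- 0.2
  # segregative direction (1,-1): eigenvalue 1/phi0 - chi, vanishing at chi_plus
  for (chi in c(0, 3, 4.999, 5.001, 8)) {
    p <- model_params(phi0 = phi0, chi = chi)
    H <- local_hessian(phi0, phi0, p)
    lam_seg <- drop(c(1, -1) %*% H %*% c(1, -1)) / 2
    expect_equal(lam_seg, 1 / phi0 - chi, tolerance = 1e-12)
    expect_identical(lam_seg > 0, chi < chi_plus(phi0))
  }
  H <- local_hessian(phi0, phi0, model_params(phi0 = phi0, chi = 5))
  expect_equal(drop(c(1, -1) %*% H %*% c(1, -1)) / 2, 0, tolerance = 1e-12)
  # associative direction (1,1): eigenvalue 1/phi0 + 2/(1-2 phi0) + chi,
  # vanishing at the associative spinodal -25/3 for phi0 = 0.2
  for (chi in c(-25 / 3 - 0.01, -25 / 3 + 0.01)) {
    H <- local_hessian(phi0, phi0, model_params(phi0 = phi0, chi = chi))
    lam_ass <- drop(c(1, 1) %*% H %*% c(1, 1)) / 2
    expect_equal(lam_ass, 1 / phi0 + 2 / 0.6 + chi, tolerance = 1e-12)
    expect_identical(lam_ass > 0, chi > -25 / 3)
  }
})

test_that("chi_plus and chi_minus thresholds", {
  expect_identical(chi_plus(0.2), 5)
  expect_identical(chi_plus(0.25), 4)
  expect_error(chi_plus(0.6), "phi0")
  expect_equal(chi_minus(0.2), -8 * atanh(0.2) / 0.2, tolerance = 1e-14)
  expect_equal(chi_minus(0.2), -8.109302, tolerance = 1e-6)
  # continuous extension at the removable singularity
  expect_identical(chi_minus(0.25), -8)
  expect_equal(chi_minus(0.25 - 1e-7), -8, tolerance = 1e-5)
  # binodal is always less negative than the associative spinodal
  phi0s <- seq(0.01, 0.24, by = 0.01)
  expect_true(all(chi_minus(phi0s) > -(1 / phi0s + 2 / (1 - 2 * phi0s))))
})

test_that("chi_minus agrees with the independent common-tangent oracle", {
  # quick version of the full acceptance cross-check
  expect_equal(chi_minus(0.2), chi_minus_oracle(0.2), tolerance = 1e-8)
})
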