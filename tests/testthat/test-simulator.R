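test_that("grid and field-state validation", {
  g <- sim_grid(64L, dx = 0.5)
  expect_equal(g$dims, 1L)
  expect_error(sim_grid(4L), "at least 8")
  expect_error(sim_grid(c(16L, 16L), dx = 0), "dx")
  g2 <- sim_grid(c(16L, 32L))
  expect_equal(g2$dims, 2L)
  expect_error(field_state(g, rep(0.2, 63), rep(0.2, 64)), "length")
  expect_error(field_state(g, rep(0.6, 64), rep(0.6, 64)), "simplex")
  st <- field_state(g, rep(0.2, 64), rep(0.3, 64))
  expect_equal(solvent_fraction(st), rep(0.5, 64))
})

test_that("initial condition: determinism, mean, simplex guard", {
  p <- base_params()
  g <- sim_grid(512L)
  cfg <- sim_config(t_end = 1, seed = 99, noise_amplitude = 1e-3)
  s1 <- initial_condition(p, g, cfg)
  s2 <- initial_condition(p, g, cfg)
  expect_identical(s1$phiA, s2$phiA)
  expect_identical(s1$phiI, s2$phiI)
  cfg2 <- sim_config(t_end = 1, seed = 100, noise_amplitude = 1e-3)
  expect_false(identical(initial_condition(p, g, cfg2)$phiA, s1$phiA))
  expect_lt(abs(mean(s1$phiA) - 0.2), 1e-4)
  expect_lt(abs(mean(s1$phiI) - 0.2), 1e-4)
  # zero amplitude: exact homogeneous state
  s0 <- initial_condition(p, g, sim_config(t_end = 1, noise_amplitude = 0))
  expect_identical(s0$phiA, rep(0.2, 512))
  expect_error(
    initial_condition(p, g, sim_config(t_end = 1, noise_amplitude = 0.15)),
    "noise_amplitude")
  # the global RNG stream is left untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(initial_condition(p, g, cfg))
  expect_identical(stats::runif(1), before)
})

test_that("chemical potentials match the pure-R reference stencils", {
  set.seed(31)
  p <- base_params(chi = 3)
  # 1D
  g <- sim_grid(32L, dx = 0.7)
  st <- initial_condition(p, g, sim_config(t_end = 1, seed = 5,
                                           noise_amplitude = 0.05))
  mu <- full_chemical_potentials(st, p)
  ref <- ref_mu_1d(st$phiA, st$phiI, g$dx, p)
  expect_equal(mu$mu_A, ref$mu_A, tolerance = 1e-13)
  expect_equal(mu$mu_I, ref$mu_I, tolerance = 1e-13)
  dv <- flux_divergence(st, mu, p)
  expect_equal(dv$div_A, ref_div_1d(st$phiA, mu$mu_A, g$dx, p$D_A),
               tolerance = 1e-12)
  expect_equal(dv$div_I, ref_div_1d(st$phiI, mu$mu_I, g$dx, p$D_I),
               tolerance = 1e-12)
  # 2D
  g2 <- sim_grid(c(16L, 16L), dx = 1.3)
  st2 <- initial_condition(p, g2, sim_config(t_end = 1, seed = 6,
                                             noise_amplitude = 0.05))
  mu2 <- full_chemical_potentials(st2, p)
  ref2 <- ref_mu_2d(st2$phiA, st2$phiI, g2$dx, p)
  expect_equal(mu2$mu_A, ref2$mu_A, tolerance = 1e-13)
  expect_equal(mu2$mu_I, ref2$mu_I, tolerance = 1e-13)
  dv2 <- flux_divergence(st2, mu2, p)
  expect_equal(dv2$div_A, ref_div_2d(st2$phiA, mu2$mu_A, g2$dx, p$D_A),
               tolerance = 1e-12)
  # uniform fields: local value exactly, zero divergence
  su <- initial_condition(p, g, sim_config(t_end = 1, noise_amplitude = 0))
  muu <- full_chemical_potentials(su, p)
  expect_equal(muu$mu_A,
               rep(local_chemical_potentials(0.2, 0.2, p)$mu_A, 32))
  expect_equal(flux_divergence(su, muu, p)$div_A, rep(0, 32))
})

test_that("discrete Laplacian symbol: single mode and second-order limit", {
  p <- base_params(chi = 0)
  for (dx in c(1, 0.5, 0.25)) {
    N <- as.integer(64 / dx)
    g <- sim_grid(N, dx = dx)
    m <- 4L
    L <- N * dx
    q <- 2 * pi * m / L
    a <- 1e-6
    x <- grid_coords(g)
    st <- field_state(g, 0.2 + a * sin(q * x), rep(0.2, N))
    mu <- full_chemical_potentials(st, p)
    # gradient part of mu_A: w^2 * q_eff^2 * a * sin(qx) with the
    # discrete symbol q_eff^2 = (2 - 2 cos(q dx))/dx^2
    q_eff2 <- (2 - 2 * cos(q * dx)) / dx^2
    grad_part <- mu$mu_A - mean(mu$mu_A)
    # the local part is linear in the tiny perturbation: subtract it
    Haa <- local_hessian(0.2, 0.2, p)[1, 1]
    pred <- (Haa + p$w^2 * q_eff2) * a * sin(q * x)
    expect_equal(grad_part, pred, tolerance = 1e-4)
  }
  # q_eff -> q with O(dx^2) error
  expect_equal((2 - 2 * cos(0.3 * 0.1)) / 0.1^2, 0.3^2, tolerance = 1e-3)
})

test_that("flux divergence sums to zero (conservation by construction)", {
  set.seed(32)
  p <- base_params(chi = -5)
  g <- sim_grid(128L)
  st <- initial_condition(p, g, sim_config(t_end = 1, seed = 7,
                                           noise_amplitude = 0.08))
  dv <- flux_divergence(st, full_chemical_potentials(st, p), p)
  expect_lt(abs(sum(dv$div_A)), 1e-13 * max(abs(dv$div_A)) * 128)
  expect_lt(abs(sum(dv$div_I)), 1e-13 * max(abs(dv$div_I)) * 128)
})

test_that("stable_dt scales as promised", {
  p <- base_params(D_I = 10)
  g1 <- sim_grid(64L, dx = 1)
  g2 <- sim_grid(128L, dx = 0.5)
  dt1 <- stable_dt(p, g1)
  dt2 <- stable_dt(p, g2)
  expect_gt(dt1, 0)
  expect_true(dt1 > 1e-4 && dt1 < 1e-1)
  ratio <- dt1 / dt2
  expect_gt(ratio, 10)    # quartic term dominates: ~16
  expect_lt(ratio, 16.5)
  expect_equal(stable_dt(p, g1, safety = 1), 2 * dt1, tolerance = 1e-12)
})

test_that("stepping: fixed point, conservation, blow-up diagnostics", {
  p <- base_params(chi = 4, k = 0.1)
  g <- sim_grid(64L)
  hom <- initial_condition(p, g, sim_config(t_end = 1, noise_amplitude = 0))
  s1 <- step_state(hom, p, stable_dt(p, g), 100L)
  expect_identical(s1$phiA, hom$phiA)   # exact fixed point
  # k = 0: mass conserved to roundoff over many steps
  p0 <- base_params(chi = 5, k = 0)
  st <- initial_condition(p0, g, sim_config(t_end = 1, seed = 3))
  s2 <- step_state(st, p0, stable_dt(p0, g), 5000L)
  expect_lt(abs(sum(s2$phiA) - sum(st$phiA)) / sum(st$phiA), 1e-11)
  expect_lt(abs(sum(s2$phiI) - sum(st$phiI)) / sum(st$phiI), 1e-11)
  # oversized dt blows up with an informative error
  expect_error(step_state(st, p0, 1, 1000L), "reduce dt")
})

test_that("free energy is a Lyapunov functional of the reaction-free dynamics", {
  g <- sim_grid(96L)
  for (chi in c(-11, 7)) {
    p <- base_params(chi = chi, k = 0)
    cfg <- sim_config(t_end = 3, seed = 17, record_energy = TRUE)
    res <- simulate(initial_condition(p, g, cfg), p, cfg)
    expect_true(all(diff(res$energy) <=
                      1e-12 * abs(res$energy[-length(res$energy)])))
  }
})

test_that("translation equivariance of the periodic scheme", {
  p <- base_params(chi = 5)
  g <- sim_grid(64L)
  cfg <- sim_config(t_end = 5, seed = 9, noise_amplitude = 1e-3)
  st <- initial_condition(p, g, cfg)
  shift_by <- 13L
  st_sh <- field_state(g, shift1(st$phiA, shift_by),
                       shift1(st$phiI, shift_by))
  dt <- stable_dt(p, g)
  a <- step_state(st, p, dt, 2000L)
  b <- step_state(st_sh, p, dt, 2000L)
  expect_identical(shift1(a$phiA, shift_by), b$phiA)
  expect_identical(shift1(a$phiI, shift_by), b$phiI)
})

test_that("simulate: snapshots, provenance, early stop", {
  p <- base_params(chi = 0, h = 2)   # stable regime, quick decay
  g <- sim_grid(32L)
  cfg <- sim_config(t_end = 2, snapshot_every = 0.5, seed = 4)
  res <- simulate(initial_condition(p, g, cfg), p, cfg)
  expect_s3_class(res, "sim_result")
  expect_length(res$snapshots, 4)
  expect_equal(res$state$time, 2, tolerance = 0.01)
  expect_identical(res$config$seed, 4L)
  expect_identical(res$params$h, 2)
  # early stop cuts a long homogeneous run short
  cfg2 <- sim_config(t_end = 500, snapshot_every = 0.05, seed = 4,
                     early_stop = TRUE)
  res2 <- simulate(initial_condition(p, g, cfg2), p, cfg2)
  expect_lt(res2$state$time, 500)
})

test_that("ideal-diffusion limit matches the non-ideal model when chi = 0 and l >> w", {
  # with chi = 0 and pattern wavelength >> w the non-ideal transport
  # reduces to ideal diffusion with the effective matrix
  p <- model_params(phi0 = 0.2, chi = 0, h = 6, k = 0.01, D_I = 10)
  expect_gt(lsa_length_scale(p), 20)
  g <- sim_grid(128L, dx = 2)
  cfg <- sim_config(t_end = suggested_t_end(p), seed = 12)
  init <- initial_condition(p, g, cfg)
  full <- simulate(init, p, cfg)
  ideal <- simulate(init, p, cfg, model = "ideal")
  a_full <- amplitude(full$state$phiA)
  a_ideal <- amplitude(ideal$state$phiA)
  expect_gt(a_full, 0.01)   # a pattern actually formed
  expect_equal(a_ideal, a_full, tolerance = 0.05)
})

test_that("state JSON archives round-trip bit-exactly", {
  p <- base_params(chi = 2)
  g <- sim_grid(c(12L, 12L), dx = 0.5)
  cfg <- sim_config(t_end = 1, seed = 8, noise_amplitude = 0.01)
  st <- initial_condition(p, g, cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_state_json(st, f, params = p, config = cfg)
  back <- read_state_json(f)
  expect_identical(back$state$phiA, st$phiA)
  expect_identical(back$state$phiI, st$phiI)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_state_json(back$state, f2, params = back$params,
                   config = back$config)
  expect_identical(readLines(f), readLines(f2))
  expect_equal(unclass(back$params), unclass(p))
  expect_equal(back$state$grid$shape, g$shape)
})
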