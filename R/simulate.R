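#' Simulation configuration
#'
#' Time-stepping and initial-condition settings.  The time step can be
#' `"auto"` (resolved via [stable_dt()] with the given safety factor at
#' simulation time) or an explicit positive number.
#'
#' @param t_end Final time (units `w^2/D_A`, positive).
#' @param dt Time step, or `"auto"`.
#' @param snapshot_every Interval between stored snapshots (`NULL` for
#'   none beyond the final state).
#' @param seed Integer seed for the initial noise.
#' @param noise_amplitude Scale of the uniform initial perturbation
#'   (must keep the fields inside the simplex; `0` gives the exact
#'   homogeneous state).
#' @param safety Safety factor for the automatic time step, in (0, 1].
#' @param early_stop If `TRUE`, stop once the relative change of the
#'   pattern metrics over a 100-snapshot window drops below `1e-6`
#'   (requires `snapshot_every`); off by default for protocol fidelity.
#' @param record_energy If `TRUE`, record the discrete total free
#'   energy after every step.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(t_end, dt = "auto", snapshot_every = NULL,
                       seed = 1L, noise_amplitude = 1e-3, safety = 0.5,
                       early_stop = FALSE, record_energy = FALSE) {
  if (!identical(dt, "auto") &&
      (!is.numeric(dt) || length(dt) != 1L || dt <= 0))
    stop('dt must be "auto" or a single positive number', call. = FALSE)
  if (length(t_end) != 1L ||
      (!is.na(t_end) && (!is.numeric(t_end) || t_end <= 0)))
    stop("t_end must be positive (or NA, to be resolved by a driver)",
         call. = FALSE)
  t_end <- as.numeric(t_end)
  if (!is.null(snapshot_every) && snapshot_every <= 0)
    stop("snapshot_every must be positive", call. = FALSE)
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0",
                                call. = FALSE)
  if (safety <= 0 || safety > 1) stop("safety must be in (0, 1]",
                                      call. = FALSE)
  structure(list(t_end = t_end, dt = dt, snapshot_every = snapshot_every,
                 seed = as.integer(seed),
                 noise_amplitude = noise_amplitude, safety = safety,
                 early_stop = early_stop, record_energy = record_energy),
            class = "sim_config")
}

#' Seeded random initial condition
#'
#' Both fields start at `phi0` plus independent uniform noise in
#' `[-noise_amplitude, +noise_amplitude]`, drawn reproducibly from the
#' configured seed (the global RNG state is restored afterwards).  The
#' same seed yields a bit-identical state.
#'
#' @param params A [model_params()] object.
#' @param grid A [sim_grid()].
#' @param config A [sim_config()].
#' @return A [field_state()] at time 0.
#' @export
initial_condition <- function(params, grid, config) {
  validate_params(params)
  a <- config$noise_amplitude
  if (a >= params$phi0 / 2)
    stop("noise_amplitude must be below phi0/2 to respect the ",
         "composition simplex", call. = FALSE)
  n <- n_cells(grid)
  if (a == 0) {
    phiA <- rep(params$phi0, n)
    phiI <- rep(params$phi0, n)
  } else {
    noise <- with_seed(config$seed, stats::runif(2 * n, -a, a))
    phiA <- params$phi0 + noise[seq_len(n)]
    phiI <- params$phi0 + noise[n + seq_len(n)]
  }
  if (grid$dims == 2L) {
    phiA <- matrix(phiA, grid$shape[1], grid$shape[2])
    phiI <- matrix(phiI, grid$shape[1], grid$shape[2])
  }
  field_state(grid, phiA, phiI, time = 0)
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

grid_dims_nxny <- function(grid) {
  if (grid$dims == 2L) c(grid$shape[1], grid$shape[2]) else c(grid$shape, 1L)
}

#' Full exchange chemical potentials on a grid
#'
#' [local_chemical_potentials()] plus the square-gradient term
#' `-w^2 lap(phi_i)`, with the Laplacian discretized by the periodic
#' second-order 3-point (1D) or 5-point (2D) stencil.  For a uniform
#' state this equals the local value exactly.
#'
#' @param state A [field_state()].
#' @param params A [model_params()] object.
#' @return List with fields `mu_A`, `mu_I`, same shape as the state
#'   fields.
#' @export
full_chemical_potentials <- function(state, params) {
  validate_params(params)
  check_simplex(state$phiA, state$phiI, "state fields")
  nn <- grid_dims_nxny(state$grid)
  res <- cpp_full_mu(as.numeric(state$phiA), as.numeric(state$phiI),
                     nn[1], nn[2], state$grid$dx, unclass(params))
  reshape_like(res, state)
}

reshape_like <- function(lst, state) {
  if (state$grid$dims == 2L)
    lapply(lst, matrix, nrow = state$grid$shape[1],
           ncol = state$grid$shape[2])
  else lst
}

#' Divergence of the conservative fluxes
#'
#' `div(D_i phi_i grad mu_i)` per species, with chemical-potential
#' gradients on cell faces and the mobility `D_i*phi_i` averaged
#' arithmetically onto each face.  By construction the grid sum of each
#' returned field vanishes to roundoff (face fluxes telescope under
#' periodic boundaries), which is what makes the scheme conservative.
#'
#' @param state A [field_state()].
#' @param mu List with `mu_A`, `mu_I` as from
#'   [full_chemical_potentials()].
#' @param params A [model_params()] object.
#' @return List with fields `div_A`, `div_I`.
#' @export
flux_divergence <- function(state, mu, params) {
  validate_params(params)
  nn <- grid_dims_nxny(state$grid)
  res <- cpp_flux_div(as.numeric(state$phiA), as.numeric(state$phiI),
                      as.numeric(mu$mu_A), as.numeric(mu$mu_I),
                      nn[1], nn[2], state$grid$dx, unclass(params))
  reshape_like(res, state)
}

#' Stable explicit-Euler time step
#'
#' Conservative bound for the explicit scheme:
#' `dt = safety / sigma_bound` with
#' `sigma_bound = max_i D_i * phi_max * (H_max * q_max^2 + w^2 * q_max^4)
#' + 2k`, where `q_max = pi/dx` is the largest resolvable wavenumber,
#' `phi_max = 2*phi0` allows headroom above the mean fraction, and
#' `H_max` is the largest absolute entry of the local Hessian at the
#' homogeneous state.  The quartic interfacial term dominates on fine
#' grids, so refining `dx` by 2 shrinks `dt` by about 16.
#'
#' @param params A [model_params()] object.
#' @param grid A [sim_grid()].
#' @param safety Safety factor in (0, 1] (default 0.5).
#' @return A positive time step (units `w^2/D_A`).
#' @export
stable_dt <- function(params, grid, safety = 0.5) {
  validate_params(params)
  if (safety <= 0 || safety > 1) stop("safety must be in (0, 1]",
                                      call. = FALSE)
  q_max <- pi / grid$dx
  H <- local_hessian(params$phi0, params$phi0, params)
  H_max <- max(abs(H))
  phi_max <- 2 * params$phi0
  sigma_bound <- max(params$D_A, params$D_I) * phi_max *
    (H_max * q_max^2 + params$w^2 * q_max^4) + 2 * params$k
  safety / sigma_bound
}

#' Advance a state by explicit Euler steps
#'
#' `phi_i <- phi_i + dt * (flux_divergence + reaction_rates)`.  The
#' homogeneous state is an exact fixed point; with `k = 0` each
#' species' total fraction is conserved to roundoff.  If an update
#' leaves the composition simplex the integration aborts with the time,
#' location and a suggestion to reduce `dt` (blow-ups are never
#' silently clamped, since they signal an unstable step size).
#'
#' @param state A [field_state()].
#' @param params A [model_params()] object.
#' @param dt Positive time step.
#' @param n_steps Number of steps to take (default 1).
#' @return The advanced [field_state()].
#' @export
step_state <- function(state, params, dt, n_steps = 1L) {
  validate_params(params)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  nn <- grid_dims_nxny(state$grid)
  res <- cpp_run(as.numeric(state$phiA), as.numeric(state$phiI),
                 nn[1], nn[2], state$grid$dx, unclass(params), dt,
                 as.integer(n_steps), state$time, FALSE)
  out <- reshape_like(res[c("phiA", "phiI")], state)
  field_state(state$grid, out$phiA, out$phiI, time = res$t)
}

#' Run a full simulation
#'
#' Integrates the dynamics from `init` to `config$t_end`, optionally
#' storing snapshots, the per-step discrete free energy, and stopping
#' early once the pattern metrics stall (if enabled).  Seed and
#' parameters are recorded in the result for provenance.
#'
#' Set `model = "ideal"` to integrate the ideal-diffusion limit
#' instead: constant diffusivity matrix `Dmat` (defaulting to
#' [effective_diffusivity_matrix()]) acting on the Laplacians plus the
#' same reactions.  This is the first-order weak-interaction
#' approximation of the full non-ideal transport.
#'
#' @param init A [field_state()] (see [initial_condition()]).
#' @param params A [model_params()] object.
#' @param config A [sim_config()].
#' @param model `"nonideal"` (default) or `"ideal"`.
#' @param Dmat Optional 2x2 diffusivity matrix for the ideal model.
#' @return An object of class `sim_result`: list with fields `state`
#'   (final [field_state()]), `snapshots` (list of states, possibly
#'   empty), `energy` (per-step vector or `NULL`), `dt`, `params`,
#'   `config`, `model`.
#' @export
simulate <- function(init, params, config, model = c("nonideal", "ideal"),
                     Dmat = NULL) {
  model <- match.arg(model)
  validate_params(params)
  if (is.na(config$t_end))
    stop("config$t_end is NA; resolve it (e.g. via suggested_t_end()) ",
         "before calling simulate", call. = FALSE)
  dt <- if (identical(config$dt, "auto"))
    stable_dt(params, init$grid, config$safety) else config$dt
  n_total <- ceiling(config$t_end / dt)
  chunk <- if (is.null(config$snapshot_every)) n_total
           else max(1L, round(config$snapshot_every / dt))
  if (model == "ideal" && is.null(Dmat))
    Dmat <- effective_diffusivity_matrix(params)
  nn <- grid_dims_nxny(init$grid)
  phiA <- as.numeric(init$phiA)
  phiI <- as.numeric(init$phiI)
  t <- init$time
  done <- 0L
  snapshots <- list()
  energy <- if (config$record_energy) numeric(0) else NULL
  metrics_hist <- list()
  while (done < n_total) {
    nstep <- min(chunk, n_total - done)
    res <- if (model == "nonideal")
      cpp_run(phiA, phiI, nn[1], nn[2], init$grid$dx, unclass(params),
              dt, as.integer(nstep), t, isTRUE(config$record_energy))
    else
      cpp_run_ideal(phiA, phiI, nn[1], nn[2], init$grid$dx,
                    unclass(params), Dmat, dt, as.integer(nstep), t)
    phiA <- res$phiA; phiI <- res$phiI; t <- res$t
    done <- done + nstep
    if (config$record_energy && !is.null(res$energy)) {
      e <- res$energy
      energy <- c(energy, if (length(energy)) e[-1] else e)
    }
    if (!is.null(config$snapshot_every)) {
      snap <- field_state(init$grid,
                          if (init$grid$dims == 2L)
                            matrix(phiA, nn[1], nn[2]) else phiA,
                          if (init$grid$dims == 2L)
                            matrix(phiI, nn[1], nn[2]) else phiI,
                          time = t)
      snapshots[[length(snapshots) + 1L]] <- snap
      if (isTRUE(config$early_stop)) {
        metrics_hist[[length(metrics_hist) + 1L]] <-
          unlist(pattern_metrics(snap)[c("amplitude", "covariance")])
        if (metrics_stalled(metrics_hist)) break
      }
    }
  }
  final <- field_state(init$grid,
                       if (init$grid$dims == 2L) matrix(phiA, nn[1], nn[2])
                       else phiA,
                       if (init$grid$dims == 2L) matrix(phiI, nn[1], nn[2])
                       else phiI,
                       time = t)
  structure(list(state = final, snapshots = snapshots, energy = energy,
                 dt = dt, params = params, config = config, model = model),
            class = "sim_result")
}

# Relative change of amplitude/covariance over the last 100 recorded
# snapshots below 1e-6?
metrics_stalled <- function(hist, window = 100L, rtol = 1e-6) {
  if (length(hist) < window) return(FALSE)
  recent <- do.call(rbind, hist[(length(hist) - window + 1L):length(hist)])
  spread <- apply(recent, 2, function(v) diff(range(v)))
  scale <- pmax(apply(abs(recent), 2, max), 1e-12)
  all(spread / scale < rtol)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulation result (%s model): t = %g, dt = %g, seed = %d\n",
              x$model, x$state$time, x$dt, x$config$seed))
  print(x$state)
  invisible(x)
}

#' Discrete total free energy of a state
#'
#' Sum over cells of the local free-energy density plus the staggered
#' square-gradient contribution, times the cell volume.  With `k = 0`
#' the conservative dynamics are a gradient flow of this functional, so
#' it is non-increasing along trajectories at a stable time step.
#'
#' @param state A [field_state()].
#' @param params A [model_params()] object.
#' @return Total free energy (units `kB*T/nu * w^dims`).
#' @export
total_free_energy <- function(state, params) {
  validate_params(params)
  nn <- grid_dims_nxny(state$grid)
  cpp_energy(as.numeric(state$phiA), as.numeric(state$phiI),
             nn[1], nn[2], state$grid$dx, unclass(params))
}

#' Measure a single-mode linear growth rate from the simulator
#'
#' Initializes the fields with a small perturbation along the dominant
#' eigenvector of the dynamical matrix at the discrete wavenumber of
#' Fourier mode `m`, integrates briefly, and fits the slope of the log
#' modulus of the mode's Fourier coefficient against time.  Used as the
#' numerical cross-check of [dynamical_matrix()] eigenvalues: the two
#' routes (closed-form linear algebra vs. nonlinear integration) agree
#' to a couple of percent in the linear regime.
#'
#' @param params A [model_params()] object.
#' @param grid A 1D [sim_grid()].
#' @param m Fourier mode index (1 <= m <= shape/2).
#' @param amplitude Perturbation amplitude (default `1e-6`).
#' @param n_fit Number of fit samples (default 12).
#' @param horizon Integration time as a multiple of `1/|sigma|`
#'   (default 0.5; keeps the run in the linear regime).
#' @return List with `sigma_measured`, `sigma_predicted`, `q_eff`.
#' @export
measure_growth_rate <- function(params, grid, m, amplitude = 1e-6,
                                n_fit = 12L, horizon = 0.5) {
  validate_params(params)
  if (grid$dims != 1L) stop("measure_growth_rate expects a 1D grid",
                            call. = FALSE)
  N <- grid$shape
  if (m < 1 || m > N / 2) stop("mode index m out of range", call. = FALSE)
  L <- N * grid$dx
  q <- 2 * pi * m / L
  # discrete symbol of the 3-point Laplacian
  q_eff <- sqrt(2 - 2 * cos(q * grid$dx)) / grid$dx
  J <- dynamical_matrix(params, q_eff)
  ev <- eigen(J)
  i_dom <- which.max(Re(ev$values))
  sigma_pred <- Re(ev$values[i_dom])
  if (abs(Im(ev$values[i_dom])) > 1e-12 * max(1, abs(sigma_pred)))
    stop("dominant eigenvalue is complex; growth-rate fit undefined",
         call. = FALSE)
  v <- Re(ev$vectors[, i_dom])
  v <- v / max(abs(v))
  x <- grid_coords(grid)
  modeA <- amplitude * v[1] * cos(q * x)
  modeI <- amplitude * v[2] * cos(q * x)
  state <- field_state(grid, params$phi0 + modeA, params$phi0 + modeI)
  t_tot <- horizon / max(abs(sigma_pred), 1e-3)
  dt <- stable_dt(params, grid, 0.5)
  steps_per <- max(1L, ceiling(t_tot / dt / n_fit))
  coef_at <- function(st) {
    f <- st$phiA - mean(st$phiA)
    Mod(sum(f * exp(-2i * pi * m * (seq_len(N) - 1) / N))) / N
  }
  ts <- numeric(n_fit + 1)
  cs <- numeric(n_fit + 1)
  ts[1] <- state$time; cs[1] <- coef_at(state)
  for (i in seq_len(n_fit)) {
    state <- step_state(state, params, dt, steps_per)
    ts[i + 1] <- state$time
    cs[i + 1] <- coef_at(state)
  }
  if (any(cs <= 0)) stop("mode amplitude vanished during the fit",
                         call. = FALSE)
  fit <- stats::lm(log(cs) ~ ts)
  list(sigma_measured = unname(stats::coef(fit)[2]),
       sigma_predicted = sigma_pred, q_eff = q_eff)
}
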