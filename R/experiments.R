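#' Deterministic per-cell seed
#'
#' Derives an independent, reproducible seed for a scan cell from the
#' master seed and the cell's axis indices.  Always below 2^31.
#'
#' @param master Master seed (integer).
#' @param i,j Axis indices (1-based).
#' @return A single integer seed.
#' @export
cell_seed <- function(master, i, j = 1L) {
  as.integer((as.numeric(master) * 7919 + i * 104729 + j * 130363) %%
               2147483629) + 1L
}

#' Suggested grid spacing for a parameter set
#'
#' Picks `dx` from `{1, 2, 4}` (units `w`) so that the wavelength of the
#' fastest-growing linear mode is resolved by at least ~32 cells, while
#' never under-resolving the interfacial width.  For strongly
#' interacting (sharp-interface) parameters this returns 1.
#'
#' @param params A [model_params()] object.
#' @param max_dx Upper cap on the spacing (default 4).
#' @return Grid spacing in units of `w`.
#' @export
suggested_dx <- function(params, max_dx = 4) {
  ell <- tryCatch(lsa_length_scale(params), error = function(e) NA_real_)
  if (!is.finite(ell)) return(1)
  min(max_dx, max(1, 2^floor(log2(ell / 32))))
}

#' Suggested simulation time for pattern formation
#'
#' `t_end = min(cap, max(100, factor / sigma_star))` with `sigma_star`
#' the fastest linear growth rate: a fixed number of e-folding times
#' past saturation of the initial instability.  Used for runs whose
#' protocol does not pin the final time.  Stable parameters get the
#' cap.
#'
#' @param params A [model_params()] object.
#' @param factor Number of growth times (default 25).
#' @param cap Upper bound on the time (default 1e4).
#' @return Final time in units of `w^2/D_A`.
#' @export
suggested_t_end <- function(params, factor = 25, cap = 1e4) {
  d <- dispersion_relation(params)
  if (!d$unstable) return(cap)
  min(cap, max(100, factor / d$sigma_star))
}

#' Parameter-plane scan of stationary pattern metrics
#'
#' Runs one seeded simulation per cell of a rectangular parameter grid
#' and records the pattern metrics plus the linear-stability verdict
#' (the overlay of phase-diagram figures).  Cell seeds are derived
#' deterministically from the master seed and the cell indices, so the
#' scan is reproducible and insensitive to evaluation order.  Cells
#' whose integration blows up are recorded as failed and the scan
#' continues.
#'
#' @param base A [model_params()] object giving the non-swept values.
#' @param axis1,axis2 Lists `list(name = , values = )` with name in
#'   `{"chi", "h", "D_I/D_A", "k"}`.
#' @param sim A [sim_config()]; its `seed` is the master seed.
#' @param grid A [sim_grid()] used for every cell.
#' @return A data.frame of class `scan_table` with one row per cell:
#'   axis values, `amplitude`, `covariance`, `length`, `unstable_lsa`,
#'   `seed`, `failed`.  Provenance (base params, config) is attached as
#'   attributes.
#' @export
scan_phase_diagram <- function(base, axis1, axis2, sim,
                               grid = sim_grid(200L, dx = 1)) {
  validate_params(base)
  check_axis <- function(ax) {
    if (!is.list(ax) || !all(c("name", "values") %in% names(ax)))
      stop("axis spec must be list(name=, values=)", call. = FALSE)
    if (!ax$name %in% c("chi", "h", "D_I/D_A", "k"))
      stop("axis name must be one of chi, h, D_I/D_A, k", call. = FALSE)
    ax
  }
  axis1 <- check_axis(axis1); axis2 <- check_axis(axis2)
  set_axis <- function(p, name, v) {
    switch(name,
           "chi" = update_params(p, chi = v),
           "h" = update_params(p, h = v),
           "k" = update_params(p, k = v),
           "D_I/D_A" = update_params(p, D_I = v * p$D_A))
  }
  rows <- list()
  for (i in seq_along(axis1$values)) {
    for (j in seq_along(axis2$values)) {
      p <- set_axis(set_axis(base, axis1$name, axis1$values[i]),
                    axis2$name, axis2$values[j])
      seed_ij <- cell_seed(sim$seed, i, j)
      cfg <- sim
      cfg$seed <- seed_ij
      verdict <- dispersion_relation(p)$unstable
      cell <- tryCatch({
        res <- simulate(initial_condition(p, grid, cfg), p, cfg)
        m <- pattern_metrics(res$state)
        data.frame(a1 = axis1$values[i], a2 = axis2$values[j],
                   amplitude = m$amplitude, covariance = m$covariance,
                   length = m$length, unstable_lsa = verdict,
                   seed = seed_ij, failed = FALSE)
      }, error = function(e) {
        data.frame(a1 = axis1$values[i], a2 = axis2$values[j],
                   amplitude = NA_real_, covariance = NA_real_,
                   length = NA_real_, unstable_lsa = verdict,
                   seed = seed_ij, failed = TRUE)
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1:2] <- make.names(c(axis1$name, axis2$name))
  attr(out, "axis1") <- axis1$name
  attr(out, "axis2") <- axis2$name
  attr(out, "base_params") <- unclass(base)
  attr(out, "sim_config") <- unclass(sim)
  attr(out, "grid") <- unclass(grid)
  class(out) <- c("scan_table", "data.frame")
  out
}

#' Compare pattern lengths in one and two dimensions
#'
#' For each parameter set runs a 1D simulation of length `L` and a 2D
#' simulation on an `L x L` box from matched seeds, and reports the
#' dominant length scales plus their relative difference.  Parameter
#' sets whose length is undefined (no significant spectral peak)
#' propagate `NA`.
#'
#' @param params_list List of [model_params()] objects (each should be
#'   linearly unstable so a pattern forms).
#' @param sim A [sim_config()]; `t_end` may be `NULL` in which case
#'   [suggested_t_end()] is used per parameter set.
#' @param L Box length in units of `w` (default 128).
#' @param dx Grid spacing, or `NULL` to use [suggested_dx()] per set.
#' @param refine Passed to [dominant_length()]: sub-bin log-parabolic
#'   refinement of the spectral peak (recommended for small boxes,
#'   where raw bins quantize lengths in steps of `L/m`).
#' @return data.frame with columns `chi, h, D_ratio, k, l_1d, l_2d,
#'   rel_diff, seed`.
#' @export
compare_1d_2d <- function(params_list, sim, L = 128, dx = NULL,
                          refine = FALSE) {
  rows <- lapply(seq_along(params_list), function(idx) {
    p <- params_list[[idx]]
    validate_params(p)
    dxi <- if (is.null(dx)) suggested_dx(p) else dx
    n <- as.integer(round(L / dxi))
    cfg <- sim
    cfg$seed <- cell_seed(sim$seed, idx)
    if (is.null(cfg$t_end) || is.na(cfg$t_end))
      cfg$t_end <- suggested_t_end(p)
    g1 <- sim_grid(n, dx = dxi)
    g2 <- sim_grid(c(n, n), dx = dxi)
    r1 <- simulate(initial_condition(p, g1, cfg), p, cfg)
    r2 <- simulate(initial_condition(p, g2, cfg), p, cfg)
    l1 <- as.numeric(dominant_length(r1$state$phiA, dx = dxi,
                                     refine = refine))
    l2 <- as.numeric(dominant_length(r2$state$phiA, dx = dxi,
                                     refine = refine))
    data.frame(chi = p$chi, h = p$h, D_ratio = p$D_I / p$D_A, k = p$k,
               l_1d = l1, l_2d = l2,
               rel_diff = abs(l2 - l1) / l1, seed = cfg$seed)
  })
  do.call(rbind, rows)
}

#' Count connected components of the thresholded field
#'
#' Binarizes a 2D field at a threshold (the spatial median by default)
#' and counts 4-connected components of the above-threshold region with
#' periodic wraparound.  A stripe pattern yields few elongated
#' components; droplet morphologies yield many.
#'
#' @param field Numeric matrix.
#' @param threshold Binarization level (default `median(field)`).
#' @return Integer component count.
#' @export
count_components <- function(field, threshold = stats::median(field)) {
  if (!is.matrix(field)) stop("count_components expects a matrix",
                              call. = FALSE)
  nx <- nrow(field); ny <- ncol(field)
  mask <- field > threshold
  labels <- matrix(0L, nx, ny)
  comp <- 0L
  for (j0 in seq_len(ny)) {
    for (i0 in seq_len(nx)) {
      if (!mask[i0, j0] || labels[i0, j0] > 0L) next
      comp <- comp + 1L
      stack <- list(c(i0, j0))
      labels[i0, j0] <- comp
      while (length(stack) > 0) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        i <- cur[1]; j <- cur[2]
        nbrs <- rbind(
          c(if (i == nx) 1L else i + 1L, j),
          c(if (i == 1L) nx else i - 1L, j),
          c(i, if (j == ny) 1L else j + 1L),
          c(i, if (j == 1L) ny else j - 1L))
        for (r in seq_len(4)) {
          ii <- nbrs[r, 1]; jj <- nbrs[r, 2]
          if (mask[ii, jj] && labels[ii, jj] == 0L) {
            labels[ii, jj] <- comp
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  comp
}
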