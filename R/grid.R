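#' Periodic simulation grid
#'
#' Equidistant periodic grid in one or two dimensions.  The physical
#' extent per axis is `shape * dx` in units of the interfacial width
#' `w`; boundaries are always periodic.
#'
#' @param shape Integer vector of length 1 (1D) or 2 (2D): number of
#'   cells per axis, at least 8.
#' @param dx Grid spacing (units `w`), shared by all axes.
#' @return An object of class `sim_grid`.
#' @export
sim_grid <- function(shape, dx = 1) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(1L, 2L))
    stop("shape must have length 1 or 2", call. = FALSE)
  if (any(shape < 8L)) stop("grid needs at least 8 cells per axis",
                            call. = FALSE)
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0)
    stop("dx must be a single positive number", call. = FALSE)
  structure(list(dims = length(shape), shape = shape, dx = dx,
                 boundary = "periodic"),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("Periodic %dD grid: %s cells, dx = %g (length %s w)\n",
              x$dims, paste(x$shape, collapse = " x "), x$dx,
              paste(x$shape * x$dx, collapse = " x ")))
  invisible(x)
}

n_cells <- function(grid) prod(grid$shape)

#' Cell-centre coordinates of a grid axis
#'
#' @param grid A [sim_grid()].
#' @param axis Axis index (1 or 2).
#' @return Numeric vector of coordinates `(0, dx, 2*dx, ...)`.
#' @export
grid_coords <- function(grid, axis = 1) {
  (seq_len(grid$shape[axis]) - 1) * grid$dx
}

#' Discretized field state
#'
#' Volume-fraction fields of activator and inhibitor on a grid, plus
#' the elapsed non-dimensional time.  Fields must lie strictly inside
#' the open composition simplex everywhere.
#'
#' @param grid A [sim_grid()].
#' @param phiA,phiI Numeric vector (1D) or matrix (2D) matching the
#'   grid shape.
#' @param time Elapsed time (units `w^2/D_A`, non-negative).
#' @return An object of class `field_state`.
#' @export
field_state <- function(grid, phiA, phiI, time = 0) {
  if (!inherits(grid, "sim_grid")) stop("grid must be a sim_grid",
                                        call. = FALSE)
  if (grid$dims == 2L) {
    phiA <- as.matrix(phiA); phiI <- as.matrix(phiI)
    if (!all(dim(phiA) == grid$shape) || !all(dim(phiI) == grid$shape))
      stop("field dimensions do not match the grid", call. = FALSE)
  } else {
    phiA <- as.numeric(phiA); phiI <- as.numeric(phiI)
    if (length(phiA) != grid$shape || length(phiI) != grid$shape)
      stop("field length does not match the grid", call. = FALSE)
  }
  check_simplex(phiA, phiI, where = "field_state fractions")
  if (time < 0) stop("time must be non-negative", call. = FALSE)
  structure(list(grid = grid, phiA = phiA, phiI = phiI, time = time),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf(
    "Field state at t = %g: phiA in [%.4g, %.4g], phiI in [%.4g, %.4g]\n",
    x$time, min(x$phiA), max(x$phiA), min(x$phiI), max(x$phiI)))
  print(x$grid)
  invisible(x)
}

#' Solvent fraction of a state
#'
#' @param state A [field_state()].
#' @return `1 - phiA - phiI`, same shape as the fields.
#' @export
solvent_fraction <- function(state) 1 - state$phiA - state$phiI
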