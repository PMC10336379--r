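#' Model parameters for the non-ideal activator-inhibitor system
#'
#' Bundles all physical parameters of the model in non-dimensional units:
#' lengths in units of the interfacial width `w`, times in units of
#' `w^2/D_A`, and energy densities in units of `kB*T/nu` (`nu` the common
#' molecular volume).  With the defaults `D_A = 1` and `w = 1` the
#' parameter values quoted throughout the documentation (e.g.
#' `k = 0.1`) are already in internal units.
#'
#' @param phi0 Mean volume fraction of each of the activator A and the
#'   inhibitor I.  Must satisfy `0 < phi0 < 1/2` so the homogeneous
#'   solvent fraction `1 - 2*phi0` stays positive.
#' @param chi Flory interaction parameter between A and I
#'   (dimensionless); positive values are effective repulsion, negative
#'   values attraction.
#' @param h Hill exponent of the production term (`h >= 1`).
#' @param k Reaction rate constant (units `D_A/w^2`, `k >= 0`).
#' @param D_A,D_I Diffusivities of activator and inhibitor (positive;
#'   `D_A` sets the time unit).
#' @param w Interfacial width parameter (positive; sets the length unit).
#'
#' @return An object of class `model_params` (a named list with the
#'   seven fields above).
#' @examples
#' p <- model_params(phi0 = 0.2, chi = 1, h = 5, k = 0.1, D_I = 10)
#' homogeneous_state(p)
#' @export
model_params <- function(phi0 = 0.2, chi = 0, h = 5, k = 0.1,
                         D_A = 1, D_I = 1, w = 1) {
  p <- list(phi0 = phi0, chi = chi, h = h, k = k,
            D_A = D_A, D_I = D_I, w = w)
  validate_params(p)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (non-dimensional):\n")
  cat(sprintf("  phi0 = %g, chi = %g, h = %g, k = %g\n",
              x$phi0, x$chi, x$h, x$k))
  cat(sprintf("  D_A = %g, D_I = %g (ratio %g), w = %g\n",
              x$D_A, x$D_I, x$D_I / x$D_A, x$w))
  invisible(x)
}

validate_params <- function(p) {
  fields <- c("phi0", "chi", "h", "k", "D_A", "D_I", "w")
  if (!setequal(names(p), fields))
    stop("model_params requires exactly the fields: ",
         paste(fields, collapse = ", "), call. = FALSE)
  for (f in fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number",
           call. = FALSE)
  }
  if (p$phi0 <= 0 || p$phi0 >= 0.5)
    stop("phi0 must lie in (0, 1/2); got ", p$phi0, call. = FALSE)
  if (p$h < 1) stop("Hill exponent h must be >= 1; got ", p$h, call. = FALSE)
  if (p$k < 0) stop("reaction rate k must be >= 0; got ", p$k, call. = FALSE)
  if (p$D_A <= 0) stop("D_A must be positive", call. = FALSE)
  if (p$D_I <= 0) stop("D_I must be positive", call. = FALSE)
  if (p$w <= 0) stop("w must be positive", call. = FALSE)
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, running
#' the full validation again.
#'
#' @param params A [model_params()] object.
#' @param ... Named fields to replace (any of `phi0, chi, h, k, D_A,
#'   D_I, w`).
#' @return A new `model_params` object.
#' @export
update_params <- function(params, ...) {
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  bad <- setdiff(names(repl), names(params))
  if (length(bad) > 0)
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  params[names(repl)] <- repl
  validate_params(params)
  structure(params, class = "model_params")
}

#' Homogeneous steady state
#'
#' The spatially uniform fixed point of the dynamics.  Because the
#' Hill-Langmuir production evaluates to `phi0` when both fractions
#' equal `phi0` (the ratio of inhibitor to activator is 1), the reaction
#' term vanishes there for every Hill exponent, making `(phi0, phi0)`
#' a steady state irrespective of the interactions.
#'
#' @param params A [model_params()] object.
#' @return Named numeric vector `c(phiA = phi0, phiI = phi0)`.
#' @export
homogeneous_state <- function(params) {
  validate_params(params)
  c(phiA = params$phi0, phiI = params$phi0)
}

#' Serialize / deserialize model parameters
#'
#' Parameters round-trip through a flat JSON mapping whose keys are
#' exactly the seven field names of [model_params()].  Unknown keys are
#' rejected so configuration typos fail loudly.
#'
#' @param params A [model_params()] object.
#' @param path Optional file path; if `NULL`, `params_to_json` returns
#'   the JSON string.
#' @return `params_to_json`: JSON string (invisibly, if written to a
#'   file); `params_from_json`: a `model_params` object.
#' @export
params_to_json <- function(params, path = NULL) {
  validate_params(params)
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' @param x A JSON string, a file path to a JSON document, or an
#'   already-parsed named list.
#' @rdname params_to_json
#' @export
params_from_json <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
  else if (is.character(x))
    x <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  if (!is.list(x)) x <- as.list(x)
  fields <- c("phi0", "chi", "h", "k", "D_A", "D_I", "w")
  unknown <- setdiff(names(x), fields)
  if (length(unknown) > 0)
    stop("unknown parameter key(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(model_params, x)
}
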