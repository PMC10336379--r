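STATE_SCHEMA_VERSION <- "1"

#' Write a field state to a JSON archive
#'
#' Plain-text archive holding the fields, grid, time and (optionally)
#' the generating parameters and configuration, under a versioned
#' schema.  Bit-reproducible for identical inputs: numbers are
#' serialized at full precision and no timestamps are embedded.
#'
#' @param state A [field_state()].
#' @param path Output path.
#' @param params Optional [model_params()] stored for provenance.
#' @param config Optional [sim_config()] stored for provenance.
#' @return `path`, invisibly.
#' @export
write_state_json <- function(state, path, params = NULL, config = NULL) {
  doc <- list(schema_version = STATE_SCHEMA_VERSION,
              grid = list(dims = state$grid$dims,
                          shape = state$grid$shape,
                          dx = state$grid$dx),
              time = state$time,
              phiA = as.numeric(state$phiA),
              phiI = as.numeric(state$phiI))
  if (!is.null(params)) doc$params <- unclass(params)
  if (!is.null(config)) doc$config <- unclass(config)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a field state from a JSON archive
#'
#' @param path Path written by [write_state_json()].
#' @return A list with `state` ([field_state()]), and `params` /
#'   `config` when present in the archive.
#' @export
read_state_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(doc$schema_version), STATE_SCHEMA_VERSION))
    stop("unsupported state schema version: ", doc$schema_version,
         call. = FALSE)
  g <- sim_grid(doc$grid$shape, dx = doc$grid$dx)
  phiA <- doc$phiA; phiI <- doc$phiI
  if (g$dims == 2L) {
    phiA <- matrix(phiA, g$shape[1], g$shape[2])
    phiI <- matrix(phiI, g$shape[1], g$shape[2])
  }
  out <- list(state = field_state(g, phiA, phiI, time = doc$time))
  if (!is.null(doc$params)) out$params <- do.call(model_params, doc$params)
  if (!is.null(doc$config)) out$config <- do.call(sim_config, doc$config)
  out
}

#' Write a run manifest
#'
#' A JSON manifest recording everything needed to reproduce an output
#' file: command, arguments, parameters, seed, time step and package
#' version.  No timestamps, so identical runs produce identical
#' manifests.
#'
#' @param path Manifest path.
#' @param command Subcommand name.
#' @param args Named list of parsed arguments.
#' @param params Optional parameter list.
#' @param seed Optional seed.
#' @param dt Optional time step.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, args = list(), params = NULL,
                           seed = NULL, dt = NULL) {
  doc <- list(schema_version = STATE_SCHEMA_VERSION,
              tool = "turingfh",
              version = as.character(utils::packageVersion("turingfh")),
              command = command, args = args)
  if (!is.null(params)) doc$params <- unclass(params)
  if (!is.null(seed)) doc$seed <- seed
  if (!is.null(dt)) doc$dt <- dt
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

# Read a JSON (or, if the yaml package happens to be available, YAML)
# config file into a named list.
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
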