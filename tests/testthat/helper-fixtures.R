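# Shared parameter fixtures: the baseline parameter set used throughout
# the phase-diagram studies (phi0 = 0.2, k = 0.1 in units of D_A/w^2).
base_params <- function(...) {
  args <- list(phi0 = 0.2, chi = 0, h = 5, k = 0.1, D_A = 1, D_I = 5,
               w = 1)
  override <- list(...)
  args[names(override)] <- override
  do.call(model_params, args)
}

# deterministic pseudo-random point strictly inside the composition
# simplex, away from the edges
random_simplex_point <- function() {
  repeat {
    a <- stats::runif(1, 0.02, 0.6)
    b <- stats::runif(1, 0.02, 0.6)
    if (a + b < 0.95) return(c(a, b))
  }
}

random_valid_params <- function() {
  model_params(phi0 = stats::runif(1, 0.05, 0.45),
               chi = stats::runif(1, -10, 8),
               h = stats::runif(1, 1, 10),
               k = stats::runif(1, 0, 1),
               D_A = stats::runif(1, 0.5, 2),
               D_I = stats::runif(1, 0.5, 20),
               w = stats::runif(1, 0.5, 2))
}
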