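Package: turingfh
Title: Turing Patterns in Non-Ideal Fluids with Flory-Huggins Interactions
Version: 0.1.0
Authors@R:
    person("Pattern", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for an activator-inhibitor
    reaction-diffusion system whose diffusion is driven by the chemical
    potentials of a non-ideal Flory-Huggins fluid.  Provides the model
    thermodynamics (free energy, exchange chemical potentials, local
    Hessian, binodal and spinodal interaction thresholds), linear
    stability analysis of the homogeneous state (dispersion relations,
    effective cross-diffusion matrix, minimal pattern-supporting
    interaction strength), a mass-conserving staggered-grid explicit
    Euler integrator on periodic 1D and 2D grids, pattern metrics
    (amplitude, spatial covariance, structure factor, dominant length
    scale, scaling-exponent fits), and drivers for parameter-plane scans
    and 1D-versus-2D comparisons with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
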