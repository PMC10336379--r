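#' Pattern amplitude
#'
#' Half the peak-to-peak range of a field, `(max - min)/2`: the
#' amplitude of a near-sinusoidal pattern, zero for a uniform state.
#'
#' @param field Numeric vector or matrix.
#' @return Non-negative scalar (fraction units).
#' @export
amplitude <- function(field) {
  if (length(field) == 0L) stop("empty field", call. = FALSE)
  (max(field) - min(field)) / 2
}

#' Spatial covariance of activator and inhibitor
#'
#' `cov(phiA, phiI) = <phiA*phiI> - <phiA><phiI>` with `< >` the
#' spatial average over the grid.  Positive values indicate
#' co-localization (associative patterns), negative values
#' anti-correlation (segregative patterns).  Invariant under adding
#' constants to either field and symmetric in its arguments.
#'
#' @param state A [field_state()], or a numeric field (then `phiI` must
#'   be given).
#' @param phiI Second field when `state` is a plain field.
#' @return Scalar covariance (fraction^2).
#' @export
covariance <- function(state, phiI = NULL) {
  if (inherits(state, "field_state")) {
    a <- as.numeric(state$phiA); b <- as.numeric(state$phiI)
  } else {
    a <- as.numeric(state); b <- as.numeric(phiI)
    if (length(a) != length(b)) stop("fields must match in size",
                                     call. = FALSE)
  }
  mean(a * b) - mean(a) * mean(b)
}

#' Structure factor of a field
#'
#' Discrete Fourier power of the mean-subtracted field, normalized by
#' the number of cells, with the `q = 0` mode excluded.  In 1D the bins
#' are the positive Fourier modes `q_m = 2*pi*m/L`; in 2D the power is
#' radially averaged over annular bins of width `2*pi/L` anchored at
#' `q = 2*pi/L` (one Fourier shell per bin on a square box).
#'
#' @param field Numeric vector (1D) or square matrix (2D), at least 8
#'   cells per axis.
#' @param dx Grid spacing (units `w`).
#' @return An object of class `structure_factor`: list with strictly
#'   increasing `q` (> 0) and non-negative spectral power `S`.
#' @export
structure_factor <- function(field, dx = 1) {
  if (is.matrix(field)) {
    if (any(dim(field) < 8L)) stop("field needs >= 8 cells per axis",
                                   call. = FALSE)
    nx <- nrow(field); ny <- ncol(field)
    if (nx != ny) stop("2D structure factor expects a square field",
                       call. = FALSE)
    L <- nx * dx
    pw <- Mod(stats::fft(field - mean(field)))^2 / (nx * ny)
    kx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) * 2 * pi / L
    qmag <- sqrt(outer(kx^2, kx^2, "+"))
    dq <- 2 * pi / L
    bin <- round(qmag / dq)          # shell index; bin j centred at j*dq
    keep <- bin > 0
    S <- tapply(pw[keep], bin[keep], mean)
    q <- as.numeric(names(S)) * dq
    ord <- order(q)
    q <- q[ord]; S <- as.numeric(S)[ord]
  } else {
    N <- length(field)
    if (N < 8L) stop("field needs >= 8 cells", call. = FALSE)
    L <- N * dx
    pw <- Mod(stats::fft(field - mean(field)))^2 / N
    m <- seq_len(N %/% 2)
    q <- 2 * pi * m / L
    S <- pw[m + 1L]
  }
  structure(list(q = q, S = S), class = "structure_factor")
}

#' @export
as.data.frame.structure_factor <- function(x, ...) {
  data.frame(q = x$q, S = x$S)
}

#' @export
print.structure_factor <- function(x, ...) {
  ip <- which.max(x$S)
  cat(sprintf("Structure factor: %d bins, peak S = %.4g at q = %.4g\n",
              length(x$q), x$S[ip], x$q[ip]))
  invisible(x)
}

#' Dominant pattern length scale
#'
#' `l = 2*pi/q_peak` with `q_peak` the bin of maximal structure-factor
#' power (ties resolve to the smallest wavenumber).  A peak is only
#' accepted as significant when it exceeds `significance` times the
#' median spectral power, which rejects noise-dominated spectra; if no
#' significant peak exists (e.g. a homogeneous state) the length is
#' undefined and `NA` is returned with attribute `reason`.
#'
#' @param field Numeric vector or square matrix.
#' @param dx Grid spacing (units `w`).
#' @param significance Peak-significance factor (default 10).
#' @param refine If `TRUE`, apply 3-point log-parabolic sub-bin
#'   refinement of the peak position (off by default: discrete argmax
#'   is deterministic).
#' @return Length in units of `w`, or `NA_real_` if undefined.
#' @export
dominant_length <- function(field, dx = 1, significance = 10,
                            refine = FALSE) {
  sf <- structure_factor(field, dx = dx)
  ip <- which.max(sf$S)
  if (!(sf$S[ip] > significance * stats::median(sf$S)))
    return(structure(NA_real_, reason = "no significant spectral peak"))
  q_peak <- sf$q[ip]
  if (refine && ip > 1L && ip < length(sf$q) &&
      sf$S[ip - 1] > 0 && sf$S[ip + 1] > 0) {
    y <- log(sf$S[(ip - 1):(ip + 1)])
    denom <- y[1] - 2 * y[2] + y[3]
    if (denom < 0) {
      delta <- 0.5 * (y[1] - y[3]) / denom
      dq <- sf$q[ip + 1] - sf$q[ip]
      q_peak <- q_peak + delta * dq
    }
  }
  2 * pi / q_peak
}

#' Metrics of a stationary pattern
#'
#' Amplitude (half peak-to-peak of `phiA`), spatial covariance of the
#' two fields, and dominant length scale of `phiA`.
#'
#' @param state A [field_state()].
#' @param significance Peak-significance factor for the length scale.
#' @return List with fields `amplitude`, `covariance`, `length` (the
#'   latter `NA` when no significant spectral peak exists).
#' @export
pattern_metrics <- function(state, significance = 10) {
  list(amplitude = amplitude(state$phiA),
       covariance = covariance(state),
       length = as.numeric(dominant_length(state$phiA,
                                           dx = state$grid$dx,
                                           significance = significance)))
}

#' Scaling exponent of length versus rate
#'
#' Least-squares slope of `log(l)` against `log(k)`, with its standard
#' error.  For weak interactions the pattern length follows the
#' reaction-diffusion length `sqrt(D/k)` and the slope is `-1/2`;
#' in the strongly attractive regime the length is pinned near the
#' interfacial width and the slope is ~0.
#'
#' @param k Positive rates (length >= 3), or a two-column object of
#'   `(k, l)` pairs.
#' @param l Positive lengths matching `k`.
#' @return List with `slope` and `se`.
#' @export
scaling_exponent <- function(k, l = NULL) {
  if (is.null(l)) {
    k <- as.data.frame(k)
    l <- k[[2]]; k <- k[[1]]
  }
  if (length(k) < 3L) stop("need at least 3 (k, l) pairs", call. = FALSE)
  if (length(k) != length(l) || any(k <= 0) || any(l <= 0))
    stop("k and l must be positive and of equal length", call. = FALSE)
  # plain OLS in closed form (avoids lm's perfect-fit warnings on
  # synthetic exact power laws)
  x <- log(k); y <- log(l)
  n <- length(x)
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  resid <- y - mean(y) - slope * xc
  se <- sqrt(sum(resid^2) / (n - 2) / sum(xc^2))
  list(slope = slope, se = se)
}

#' Write metrics rows to CSV
#'
#' One row per state: parameter columns followed by `amplitude`,
#' `covariance`, `length` and a `defined_length` flag.
#'
#' @param rows A data.frame as produced by scan drivers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
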