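#' Speckle illumination parameters
#'
#' @param grain_px target transverse grain size in pixels, defined as the
#'   FWHM of the central peak of the intensity autocorrelation (>= 2).
#' @param modulation target speckle contrast in [0, 1]; 1 is fully
#'   developed speckle, 0 is flat illumination.
#' @param seed master seed for the pattern.
#' @return an object of class `speckle_params`.
#' @export
speckle_params <- function(grain_px = 3, modulation = 1, seed = 1L) {
  if (!is.numeric(grain_px) || grain_px < 2)
    hilo_abort("grain_px must be >= 2", "parameter")
  if (!is.numeric(modulation) || modulation < 0 || modulation > 1)
    hilo_abort("modulation must lie in [0, 1]", "parameter")
  structure(list(grain_px = grain_px, modulation = modulation,
                 seed = as.integer(seed)),
            class = "speckle_params")
}

# Pupil radius (cycles/pixel) giving an intensity-autocorrelation FWHM of
# `grain_px`: for a uniform disk pupil the field correlation is a jinc whose
# squared modulus halves at 2*pi*rho*delta = 1.616, hence FWHM = 0.5145/rho.
grain_to_pupil_radius <- function(grain_px) 0.5145 / grain_px

#' Generate a fully developed laser speckle pattern
#'
#' Pupil-phase method: unit amplitudes with uniform random phases on a
#' centred disk in the frequency plane (radius inversely proportional to
#' the grain size), zero outside; the intensity is the squared modulus of
#' the inverse transform, normalized to mean 1. Partial modulation m mixes
#' the pattern with a constant: `(1 - m) + m * speckle`.
#'
#' @param shape integer vector `c(n_rows, n_cols)`.
#' @param params a [speckle_params()].
#' @return a non-negative matrix with mean 1.
#' @export
#' @examples
#' s <- generate_speckle(c(128, 128), speckle_params(grain_px = 6, seed = 2))
#' sd(s) / mean(s)          # ~1 for fully developed speckle
#' estimate_grain_size(s)   # ~6
generate_speckle <- function(shape, params) {
  if (!inherits(params, "speckle_params"))
    hilo_abort("`params` must be speckle_params()", "type")
  nr <- shape[1]; nc <- shape[2]
  if (params$grain_px >= min(nr, nc) / 4)
    hilo_abort("grain_px too large for the requested shape", "parameter")
  grid <- frequency_grid(nr, nc)
  mask <- grid$radial <= grain_to_pupil_radius(params$grain_px)
  if (sum(mask) < 8)
    hilo_abort("grain_px too small for the requested shape", "parameter")
  spec <- with_seed(params$seed, {
    F <- matrix(0 + 0i, nr, nc)
    F[mask] <- exp(2i * pi * stats::runif(sum(mask)))
    I <- Mod(stats::fft(F, inverse = TRUE))^2
    I / mean(I)
  })
  (1 - params$modulation) + params$modulation * spec
}

#' Estimate the speckle grain size of a pattern
#'
#' FWHM of the central peak of the mean-subtracted spatial autocorrelation,
#' averaged over the row and column axes, with linear interpolation between
#' samples.
#'
#' @param speckle a 2-D raster with positive mean.
#' @return grain size in pixels.
#' @export
estimate_grain_size <- function(speckle) {
  check_matrix(speckle)
  if (mean(speckle) <= 0)
    hilo_abort("speckle mean must be positive", "data")
  x <- speckle - mean(speckle)
  if (stats::sd(x) == 0)
    hilo_abort("flat image: autocorrelation has no peak", "no_peak")
  ac <- Re(stats::fft(Mod(stats::fft(x))^2, inverse = TRUE)) / length(x)
  ac <- ac / ac[1, 1]
  half_width <- function(p) {
    i <- which(p < 0.5)[1]
    if (is.na(i) || i < 2)
      hilo_abort("autocorrelation peak too wide for image", "no_peak")
    (i - 2) + (p[i - 1] - 0.5) / (p[i - 1] - p[i])
  }
  # symmetric peak: FWHM = 2 * one-sided half width, per axis
  (2 * half_width(ac[1, ]) + 2 * half_width(ac[, 1])) / 2
}

#' Uniform illumination as an average of independent speckle patterns
#'
#' Emulates a rotating diffuser: the mean of `n_realizations` independent
#' speckle patterns (seeds derived from `params$seed`), whose residual
#' contrast falls as 1/sqrt(n).
#'
#' @param shape integer vector `c(n_rows, n_cols)`.
#' @param params a [speckle_params()].
#' @param n_realizations number of independent patterns (>= 1).
#' @return a non-negative matrix with mean 1.
#' @export
uniform_illumination <- function(shape, params, n_realizations = 100L) {
  if (!inherits(params, "speckle_params"))
    hilo_abort("`params` must be speckle_params()", "type")
  n <- as.integer(n_realizations)
  if (n < 1) hilo_abort("n_realizations must be >= 1", "parameter")
  acc <- matrix(0, shape[1], shape[2])
  for (i in seq_len(n)) {
    pi_ <- params
    pi_$seed <- derive_seed(params$seed, i)
    acc <- acc + generate_speckle(shape, pi_)
  }
  acc / n
}
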