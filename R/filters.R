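#' Radially symmetric Fourier-domain Gaussian filters
#'
#' HiLo reconstruction is built from three radially symmetric gains defined
#' on the discrete Fourier frequency grid, in cycles/pixel: a Gaussian
#' high-pass HP with half-gain at the cut-off frequency k_c, its exact
#' complement LP = 1 - HP, and a difference-of-Gaussians bandpass
#' BP(k) = exp(-k^2 / (4 sigma^2)) - exp(-k^2 / (2 sigma^2)) used to isolate
#' the speckle scales before contrast evaluation.
#'
#' @name hilo-filters
NULL

fft_freq <- function(n) {
  c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / n
}

#' Build the radial frequency grid for an image size
#'
#' Per-bin radial frequency magnitude |k| in cycles/pixel, laid out in the
#' DFT bin order used by [stats::fft()]: the zero-frequency bin is element
#' (1, 1) and each axis runs 0, 1/n, ..., then the negative frequencies.
#'
#' @param n_rows,n_cols image dimensions (each >= 8).
#' @return an object of class `frequency_grid`: a list with `radial`
#'   (matrix of |k|) and `dim`.
#' @export
#' @examples
#' g <- frequency_grid(8, 8)
#' g$radial[1, 1]          # DC bin: 0
#' g$radial[5, 5]          # Nyquist corner: sqrt(0.5)
frequency_grid <- function(n_rows, n_cols) {
  if (n_rows < 8 || n_cols < 8)
    hilo_abort("frequency grid dimensions must be >= 8", "size")
  fr <- fft_freq(n_rows)
  fc <- fft_freq(n_cols)
  kr <- sqrt(outer(fr^2, fc^2, "+"))
  structure(list(radial = kr, dim = c(n_rows, n_cols)),
            class = "frequency_grid")
}

new_filter_profile <- function(gains, kind, parameter, dim) {
  structure(list(gains = gains, kind = kind, parameter = parameter,
                 dim = dim),
            class = "hilo_filter")
}

# Frequency-domain standard deviation giving half gain at k_c.
hp_freq_sd <- function(k_c) k_c / sqrt(2 * log(2))

#' Gaussian high-pass filter with half gain at the cut-off frequency
#'
#' HP(k) = 1 - exp(-k^2 / (2 s^2)) with s = k_c / sqrt(2 log 2), so that
#' HP(k_c) = 1/2 exactly and HP rises monotonically from 0 at DC to ~1.
#'
#' @param grid a [frequency_grid()].
#' @param k_c cut-off frequency in cycles/pixel, 0 < k_c < 0.5.
#' @return a `hilo_filter` of kind `"highpass"`.
#' @export
gaussian_highpass <- function(grid, k_c) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (!is.numeric(k_c) || length(k_c) != 1 || k_c <= 0 || k_c >= 0.5)
    hilo_abort("k_c must lie in (0, 0.5) cycles/pixel", "parameter")
  s <- hp_freq_sd(k_c)
  gains <- 1 - exp(-grid$radial^2 / (2 * s^2))
  new_filter_profile(gains, "highpass", k_c, grid$dim)
}

#' Low-pass complement of a high-pass filter
#'
#' LP = 1 - HP bin for bin, so LP + HP = 1 exactly and LP(k_c) = 1/2.
#'
#' @param hp a high-pass `hilo_filter`.
#' @return a `hilo_filter` of kind `"lowpass"`.
#' @export
lowpass_complement <- function(hp) {
  if (!inherits(hp, "hilo_filter") || hp$kind != "highpass")
    hilo_abort("`hp` must be a highpass filter profile", "type")
  new_filter_profile(1 - hp$gains, "lowpass", hp$parameter, hp$dim)
}

#' Difference-of-Gaussians bandpass filter
#'
#' BP(k) = exp(-k^2 / (4 sigma^2)) - exp(-k^2 / (2 sigma^2)): zero at DC,
#' non-negative everywhere, with a single radial maximum of 1/4 at
#' k = 2 sigma sqrt(log 2).
#'
#' @param grid a [frequency_grid()].
#' @param sigma_bp bandpass width sigma in cycles/pixel, positive; above
#'   the Nyquist frequency 0.5 the profile flattens over the representable
#'   band.
#' @return a `hilo_filter` of kind `"bandpass"`.
#' @export
bandpass_filter <- function(grid, sigma_bp) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (!is.numeric(sigma_bp) || length(sigma_bp) != 1 ||
      !is.finite(sigma_bp) || sigma_bp <= 0)
    hilo_abort("sigma_bp must be a positive finite number", "parameter")
  k2 <- grid$radial^2
  gains <- exp(-k2 / (4 * sigma_bp^2)) - exp(-k2 / (2 * sigma_bp^2))
  new_filter_profile(gains, "bandpass", sigma_bp, grid$dim)
}

#' Apply a Fourier-domain gain to an image
#'
#' Forward FFT, per-bin multiplication by the filter gains, inverse FFT;
#' the (numerically negligible) imaginary residue is discarded. The image
#' is treated as periodic; no padding or apodization is applied here --
#' tiled processing with halos handles edge effects on large frames.
#'
#' @param image 2-D numeric matrix with finite values.
#' @param profile a `hilo_filter` built on a grid matching `dim(image)`.
#' @return a real matrix of the same dimensions.
#' @export
apply_filter <- function(image, profile) {
  check_matrix(image)
  if (!inherits(profile, "hilo_filter"))
    hilo_abort("`profile` must be a hilo_filter", "type")
  if (!identical(dim(image), as.integer(profile$dim)) &&
      !identical(as.numeric(dim(image)), as.numeric(profile$dim)))
    hilo_abort("image dimensions do not match filter grid", "shape")
  Re(stats::fft(stats::fft(image) * profile$gains, inverse = TRUE)) /
    length(image)
}

#' @export
print.hilo_filter <- function(x, ...) {
  unit <- if (x$kind == "bandpass") "sigma_bp" else "k_c"
  cat(sprintf("<hilo_filter> %s, %s = %.4g cycles/pixel, grid %dx%d\n",
              x$kind, unit, x$parameter, x$dim[1], x$dim[2]))
  invisible(x)
}
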