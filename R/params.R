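#' Resolve HiLo algorithm parameters from the sectioning parameter sigma
#'
#' A single user-facing parameter sigma (>= 1) controls the optical section
#' thickness. Under the default calibration, sigma = 1 corresponds to a
#' bandpass width of 1/10 cycles/pixel, the lowest setting at which section
#' thickness depends linearly on sigma; from there
#' \itemize{
#'   \item `sigma_bp = sigma / 10` cycles/pixel (bandpass width),
#'   \item `k_c = 0.18 * sigma_bp` cycles/pixel (high/low-pass cut-off),
#'   \item `window_side = 1 / (2 k_c)` rounded to the nearest odd integer
#'         (side of the sliding contrast-evaluation window, pixels).
#' }
#' Individual fields can be overridden after validation; overriding
#' `window_side` is the usual way to adapt the contrast window to a coarse
#' speckle grain (several grains must fit in the window to avoid
#' speckle-leakage artifacts).
#'
#' @param sigma sectioning parameter, >= 1 (the calibrated linear regime).
#' @param sigma_bp optional override, cycles/pixel; values above the
#'   Nyquist frequency 0.5 are accepted with a warning (the bandpass
#'   flattens over the representable band and sectioning saturates).
#' @param k_c optional override, cycles/pixel in (0, 0.5).
#' @param window_side optional override, odd integer >= 3.
#' @param eta optional fixed fusion factor (skips spectral estimation).
#' @param clamp_negative if `TRUE`, negative output values are clamped to 0
#'   in the final image (the fused intermediates are kept unclamped).
#' @return an object of class `hilo_params`.
#' @export
#' @examples
#' hilo_params(1)   # sigma_bp = 0.1, k_c = 0.018, window 27
#' hilo_params(2)   # sigma_bp = 0.2, k_c = 0.036, window 13
hilo_params <- function(sigma, sigma_bp = NULL, k_c = NULL,
                        window_side = NULL, eta = NULL,
                        clamp_negative = FALSE) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma))
    hilo_abort("sigma must be a single finite number", "parameter")
  if (sigma < 1)
    hilo_abort(paste("sigma must be >= 1: the calibration places the",
                     "linear sectioning regime at sigma >= 1"),
               "below_calibration")
  sbp <- if (is.null(sigma_bp)) sigma / 10 else sigma_bp
  if (!is.numeric(sbp) || sbp <= 0 || !is.finite(sbp))
    hilo_abort("sigma_bp must be a positive finite number", "parameter")
  if (sbp > 0.5)
    hilo_warn(paste("sigma_bp exceeds the Nyquist frequency (0.5",
                    "cycles/pixel); the bandpass flattens over the",
                    "representable band and sectioning saturates"),
              "parameter")
  kc <- if (is.null(k_c)) 0.18 * sbp else k_c
  if (kc <= 0 || kc >= 0.5)
    hilo_abort("k_c must lie in (0, 0.5) cycles/pixel", "parameter")
  w <- if (is.null(window_side)) round_odd(1 / (2 * kc)) else window_side
  if (w %% 2 == 0 || w < 3)
    hilo_abort("window_side must be an odd integer >= 3", "parameter")
  if (!is.null(eta) && (!is.numeric(eta) || eta <= 0))
    hilo_abort("eta override must be a positive number", "parameter")
  structure(list(sigma = sigma, sigma_bp = sbp, k_c = kc,
                 window_side = as.integer(w), eta = eta,
                 clamp_negative = isTRUE(clamp_negative)),
            class = "hilo_params")
}

# Nearest odd integer (27.78 -> 27, 13.89 -> 13).
round_odd <- function(x) 2L * as.integer(round((x - 1) / 2)) + 1L

#' @export
print.hilo_params <- function(x, ...) {
  cat(sprintf(
    paste0("HiLo parameters: sigma = %g\n",
           "  sigma_bp    = %.4g cycles/pixel\n",
           "  k_c         = %.4g cycles/pixel\n",
           "  window_side = %d px\n"),
    x$sigma, x$sigma_bp, x$k_c, x$window_side))
  if (!is.null(x$eta)) cat(sprintf("  eta (fixed) = %.4g\n", x$eta))
  if (x$clamp_negative) cat("  negative output clamped to 0\n")
  invisible(x)
}

#' Co-registered uniform/speckle illumination image pair
#'
#' The raw input of the HiLo reconstruction: one widefield image under
#' uniform illumination (`uniform`, i_u) and one under stationary laser
#' speckle (`speckle`, i_s), pixel-registered and equally sized.
#'
#' @param uniform,speckle 2-D numeric matrices, all values finite and
#'   non-negative; `uniform` must contain at least one positive value.
#' @param pixel_size_um optional pixel pitch in microns.
#' @return an object of class `hilo_pair`.
#' @export
image_pair <- function(uniform, speckle, pixel_size_um = NULL) {
  check_matrix(uniform); check_matrix(speckle)
  check_same_dim(uniform, speckle, "uniform and speckle images")
  if (any(uniform < 0) || any(speckle < 0))
    hilo_abort("image values must be non-negative", "data")
  if (!any(uniform > 0))
    hilo_abort("uniform image has no positive values", "data")
  structure(list(uniform = uniform, speckle = speckle,
                 pixel_size_um = pixel_size_um),
            class = "hilo_pair")
}

#' @export
print.hilo_pair <- function(x, ...) {
  cat(sprintf("<hilo_pair> %d x %d", nrow(x$uniform), ncol(x$uniform)))
  if (!is.null(x$pixel_size_um))
    cat(sprintf(", %.4g um/pixel", x$pixel_size_um))
  cat("\n")
  invisible(x)
}
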