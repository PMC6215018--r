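#' HiLo optical-sectioning reconstruction
#'
#' Fuses a uniform-illumination widefield image with a speckle-illumination
#' image of the same field into an optically sectioned image. The high
#' spatial frequencies are inherently in focus and are taken directly from
#' a Gaussian high-pass of the uniform image. The in-focus low frequencies
#' are recovered by weighting the uniform image with the local contrast of
#' the bandpass-filtered difference image (speckle minus uniform): imaged
#' speckle contrast decays to zero with defocus, so the contrast map acts
#' as an in-focus mask for the coarse structure. A scalar eta matches the
#' two spectra at the cut-off frequency and the sectioned image is
#' `i_HP + eta * i_LP`.
#'
#' @param pair an [image_pair()].
#' @param sigma sectioning parameter (>= 1); ignored when `params` is given.
#' @param params a [hilo_params()] object; defaults to `hilo_params(sigma)`.
#' @return an object of class `hilo` with components
#'   \describe{
#'     \item{hilo}{the sectioned image.}
#'     \item{highpassed_uniform}{high-pass of the uniform image (the "Hi").}
#'     \item{lofreq}{low-pass of the weighted uniform image (the "Lo").}
#'     \item{weighted_uniform}{uniform image times the contrast map.}
#'     \item{difference}{speckle minus uniform, unclamped.}
#'     \item{contrast}{the local contrast map (class `contrast_map`).}
#'     \item{eta}{fusion scaling factor.}
#'     \item{params}{the resolved parameters.}
#'     \item{warnings}{character vector of processing warnings.}
#'   }
#' @seealso [section_thickness()], [hilo_tiled()], [render_pair()]
#' @export
#' @examples
#' mod <- imaging_model(photon_scale = 0, read_sd = 0)
#' sp  <- bilayer_phantom(21, c(96, 96), mod)
#' pr  <- render_pair(sp, mod, 0, speckle_params(grain_px = 3, seed = 1),
#'                    n_uniform = 50, seed = 1)
#' res <- hilo(pr, sigma = 2)
#' res$eta
hilo <- function(pair, sigma = 1, params = hilo_params(sigma)) {
  if (!inherits(pair, "hilo_pair"))
    hilo_abort("`pair` must be an image_pair()", "type")
  if (!inherits(params, "hilo_params"))
    hilo_abort("`params` must be a hilo_params()", "type")
  iu <- pair$uniform
  grid <- frequency_grid(nrow(iu), ncol(iu))
  hp <- gaussian_highpass(grid, params$k_c)
  lp <- lowpass_complement(hp)
  bp <- bandpass_filter(grid, params$sigma_bp)

  id   <- difference_image(pair)
  idbp <- apply_filter(id, bp)
  cmap <- local_contrast(idbp, iu, params$window_side)
  isu  <- weighted_uniform(iu, cmap)
  ilp  <- apply_filter(isu, lp)
  ihp  <- apply_filter(iu, hp)

  warnings <- character()
  if (is.null(params$eta)) {
    eta_est <- compute_eta(ihp, ilp, params$k_c)
    eta <- eta_est$eta
    if (eta_est$degenerate)
      warnings <- c(warnings, "degenerate spectrum: eta fixed at 1")
  } else {
    eta <- params$eta
  }

  out <- ihp + eta * ilp
  final <- if (params$clamp_negative) pmax(out, 0) else out

  structure(list(hilo = final, highpassed_uniform = ihp, lofreq = ilp,
                 weighted_uniform = isu, difference = id, contrast = cmap,
                 eta = eta, params = params,
                 pixel_size_um = pair$pixel_size_um,
                 unclamped = out, warnings = warnings),
            class = "hilo")
}

#' Difference image: speckle minus uniform
#'
#' Subtracting the uniform image removes the specimen-induced bias so the
#' local contrast is evaluated on the illumination modulation alone.
#' Signed values are retained.
#'
#' @param pair an [image_pair()].
#' @return a signed matrix.
#' @export
difference_image <- function(pair) {
  if (!inherits(pair, "hilo_pair"))
    hilo_abort("`pair` must be an image_pair()", "type")
  pair$speckle - pair$uniform
}

#' Local speckle contrast map
#'
#' Per pixel, the quotient of the population standard deviation of the
#' bandpass-filtered difference image and the local mean of the uniform
#' image, both over a sliding square window of odd side `window_side`
#' (reflective padding at the borders). The difference image is close to
#' zero-mean by construction, so its own local mean would make the quotient
#' singular; the uniform image is the bias whose removal the difference
#' performs and supplies the physically meaningful denominator.
#' Neighbourhoods whose uniform mean falls below `1e-6` of the global
#' uniform mean carry no signal and get contrast 0.
#'
#' @param difference_bp bandpass-filtered difference image.
#' @param uniform the uniform-illumination image.
#' @param window_side odd integer >= 3, smaller than both image dimensions.
#' @return an object of class `contrast_map`: list with `values` (matrix of
#'   non-negative contrasts) and `window_side`.
#' @export
local_contrast <- function(difference_bp, uniform, window_side) {
  check_matrix(difference_bp); check_matrix(uniform)
  check_same_dim(difference_bp, uniform)
  w <- as.integer(window_side)
  if (w %% 2 == 0) hilo_abort("window_side must be odd", "parameter")
  if (w >= nrow(uniform) || w >= ncol(uniform))
    hilo_abort("window_side too large for image", "configuration")
  m1 <- box_mean(difference_bp, w)
  m2 <- box_mean(difference_bp^2, w)
  sdv <- sqrt(pmax(m2 - m1^2, 0))
  mu <- box_mean(uniform, w)
  floor_mu <- 1e-6 * mean(uniform)
  cvals <- ifelse(mu > floor_mu, sdv / pmax(mu, floor_mu), 0)
  cvals[!is.finite(cvals) | cvals < 0] <- 0
  structure(list(values = cvals, window_side = w), class = "contrast_map")
}

#' Weight the uniform image by the local contrast map
#'
#' @param uniform the uniform-illumination image.
#' @param contrast a `contrast_map` (or bare matrix) of matching size.
#' @return the weighted image, elementwise `uniform * contrast`.
#' @export
weighted_uniform <- function(uniform, contrast) {
  check_matrix(uniform)
  cvals <- if (inherits(contrast, "contrast_map")) contrast$values
           else contrast
  check_matrix(cvals, "contrast")
  check_same_dim(uniform, cvals)
  uniform * cvals
}

#' Spectral fusion factor eta
#'
#' Ratio of the mean Fourier magnitudes of the high-pass and low-pass
#' components over a one-bin-wide radial annulus at the cut-off frequency
#' k_c. A point evaluation at k_c would be noise-dominated; azimuthal
#' averaging over the annulus is the stable estimator of the radial
#' spectrum there. If the low-frequency annulus average is numerically
#' zero (e.g. identical input images give an all-zero weighted image),
#' eta falls back to 1 with a degenerate-spectrum warning.
#'
#' @param highpassed_uniform,lofreq the two component images.
#' @param k_c cut-off frequency in cycles/pixel.
#' @return a list with `eta` (positive scalar) and `degenerate` (flag).
#' @export
compute_eta <- function(highpassed_uniform, lofreq, k_c) {
  check_matrix(highpassed_uniform); check_matrix(lofreq)
  check_same_dim(highpassed_uniform, lofreq)
  n <- dim(highpassed_uniform)
  grid <- frequency_grid(n[1], n[2])
  half_bin <- 0.5 / min(n)
  annulus <- abs(grid$radial - k_c) <= half_bin
  annulus[1, 1] <- FALSE
  if (!any(annulus))
    hilo_abort("empty spectral annulus: image too small for k_c",
               "configuration")
  a_hp <- mean(Mod(stats::fft(highpassed_uniform))[annulus])
  a_lp <- mean(Mod(stats::fft(lofreq))[annulus])
  eps <- 1e-12 * max(a_hp, 1)
  if (a_lp < eps) {
    return(list(eta = 1, degenerate = TRUE))
  }
  list(eta = a_hp / a_lp, degenerate = FALSE)
}

#' @export
print.hilo <- function(x, ...) {
  d <- dim(x$hilo)
  cat(sprintf("HiLo reconstruction, %d x %d px\n", d[1], d[2]))
  cat(sprintf("  sigma = %g (sigma_bp %.3g, k_c %.3g cycles/pixel, window %d px)\n",
              x$params$sigma, x$params$sigma_bp, x$params$k_c,
              x$params$window_side))
  cat(sprintf("  eta = %.4g\n", x$eta))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.hilo <- function(object, ...) {
  s <- list(
    dim = dim(object$hilo),
    params = object$params,
    eta = object$eta,
    range = range(object$hilo),
    mean_contrast = mean(object$contrast$values),
    negative_fraction = mean(object$unclamped < 0),
    warnings = object$warnings
  )
  class(s) <- "summary.hilo"
  s
}

#' @export
print.summary.hilo <- function(x, ...) {
  cat(sprintf("HiLo reconstruction summary (%d x %d px)\n",
              x$dim[1], x$dim[2]))
  print(x$params)
  cat(sprintf("  eta             = %.4g\n", x$eta))
  cat(sprintf("  output range    = [%.4g, %.4g]\n", x$range[1], x$range[2]))
  cat(sprintf("  mean contrast   = %.4g\n", x$mean_contrast))
  cat(sprintf("  negative pixels = %.2f%%\n", 100 * x$negative_fraction))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.matrix.hilo <- function(x, ...) x$hilo

#' Display a HiLo reconstruction
#'
#' Shows the sectioned image (or one of its intermediates) as a grayscale
#' raster.
#'
#' @param x a `hilo` object.
#' @param which component to display.
#' @param ... passed to [graphics::image()].
#' @export
plot.hilo <- function(x, which = c("hilo", "uniform_highpass", "lofreq",
                                   "contrast", "weighted_uniform"), ...) {
  which <- match.arg(which)
  img <- switch(which,
                hilo = x$hilo,
                uniform_highpass = x$highpassed_uniform,
                lofreq = x$lofreq,
                contrast = x$contrast$values,
                weighted_uniform = x$weighted_uniform)
  graphics::image(t(img[nrow(img):1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  asp = nrow(img) / ncol(img), main = which, ...)
  invisible(x)
}
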