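#' Gaussian FWHM of a one-pixel horizontal line profile
#'
#' Least-squares fit of `A * exp(-(x - x0)^2 / (2 w^2)) + b` to a single
#' image row, initialised from the profile's maximum, centroid and second
#' moment; returns `2 sqrt(2 log 2) * w`. The profile must show a prominent
#' peak (above three times the profile noise level).
#'
#' @param image 2-D raster.
#' @param row row index of the profile.
#' @return FWHM in pixels.
#' @export
fit_line_fwhm <- function(image, row) {
  check_matrix(image)
  if (row < 1 || row > nrow(image))
    hilo_abort("row out of range", "parameter")
  y <- as.numeric(image[row, ])
  x <- seq_along(y)
  noise_sd <- stats::mad(diff(y)) / sqrt(2)
  base0 <- stats::median(y)
  prominence <- max(y) - base0
  if (prominence <= 0 ||
      (noise_sd > 0 && prominence < 3 * noise_sd) ||
      (noise_sd == 0 && prominence < .Machine$double.eps^0.5 * max(abs(y), 1)))
    hilo_abort(sprintf("row %d: no prominent peak to fit", row),
               "fit_failure")
  # initialise from a lightly smoothed profile: max, half-max width,
  # centroid above half max
  ys <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  i_max <- which.max(ys)
  half <- base0 + (ys[i_max] - base0) / 2
  above <- ys > half
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  run_i <- which(runs$values & ends >= i_max &
                 (ends - runs$lengths + 1) <= i_max)[1]
  w_init <- if (is.na(run_i)) {
    yp <- pmax(y - base0, 0)
    sqrt(sum((x - sum(x * yp) / sum(yp))^2 * yp) / sum(yp))
  } else runs$lengths[run_i] / (2 * sqrt(2 * log(2)))
  if (!is.finite(w_init) || w_init < 0.75) w_init <- 2
  fit <- NULL
  for (wi in unique(c(w_init, w_init * 2, w_init / 2, 5))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-(x - x0)^2 / (2 * w^2)) + b,
        data = list(x = x, y = y),
        start = list(A = prominence, x0 = i_max, w = wi, b = base0),
        lower = c(A = 0, x0 = 1, w = 0.5, b = -Inf),
        upper = c(A = Inf, x0 = length(y), w = length(y), b = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    hilo_abort(sprintf("row %d: Gaussian fit failed to converge", row),
               "fit_failure")
  w <- abs(stats::coef(fit)[["w"]])
  2 * sqrt(2 * log(2)) * w
}

#' Optical section thickness from a tilted-layer image
#'
#' The tilted-layer procedure: Gaussian fits to `n_lines` one-pixel
#' horizontal line profiles, evenly spaced within the central 50% of image
#' rows, give lateral FWHMs of the in-focus strip; the known tilt converts
#' each to an axial FWHM
#' (`fwhm_px * pixel_size_um * height_difference / base_length`). The mean
#' over lines is the optical section thickness.
#'
#' @param image processed (or widefield) image of the tilted layer.
#' @param geometry a [tilt_geometry()].
#' @param pixel_size_um pixel pitch, microns.
#' @param n_lines number of line profiles (default five).
#' @return an object of class `section_measurement` with fields
#'   `per_line_fwhm_px`, `rows`, `mean_thickness_um`, `sd_thickness_um`,
#'   `geometry`, `pixel_size_um`.
#' @export
section_thickness <- function(image, geometry, pixel_size_um,
                              n_lines = 5L) {
  check_matrix(image)
  if (!inherits(geometry, "tilt_geometry"))
    hilo_abort("`geometry` must be tilt_geometry()", "type")
  if (n_lines < 1) hilo_abort("n_lines must be >= 1", "parameter")
  nr <- nrow(image)
  lo <- ceiling(nr * 0.25); hi <- floor(nr * 0.75)
  rows <- unique(round(seq(lo, hi, length.out = n_lines)))
  fwhms <- vapply(rows, function(r) fit_line_fwhm(image, r), numeric(1))
  if (geometry$slope == 0)
    hilo_warn("zero tilt: axial conversion factor is 0", "degenerate_geometry")
  th <- fwhms * pixel_size_um * geometry$slope
  structure(list(per_line_fwhm_px = fwhms, rows = rows,
                 mean_thickness_um = mean(th),
                 sd_thickness_um = stats::sd(th),
                 geometry = geometry, pixel_size_um = pixel_size_um),
            class = "section_measurement")
}

#' @export
print.section_measurement <- function(x, ...) {
  sdtxt <- if (is.na(x$sd_thickness_um)) "NA"
           else sprintf("%.2f", x$sd_thickness_um)
  cat(sprintf(
    "Optical section thickness: %.2f +/- %s um (%d lines, tilt %.4g)\n",
    x$mean_thickness_um, sdtxt, length(x$per_line_fwhm_px),
    x$geometry$slope))
  invisible(x)
}

#' Section thickness as a function of the sectioning parameter
#'
#' Reprocesses the same raw image pair at each sigma (no reacquisition)
#' and measures the section thickness each time with the tilted-layer
#' procedure.
#'
#' @param pair an [image_pair()] of the tilted layer.
#' @param geometry a [tilt_geometry()].
#' @param pixel_size_um pixel pitch, microns.
#' @param sigma_list ascending sigmas, all >= 1.
#' @param n_lines line profiles per measurement.
#' @return an object of class `sigma_sweep`: a data frame with columns
#'   `sigma`, `mean_thickness_um`, `sd_thickness_um` and attribute
#'   `measurements` (list of `section_measurement`).
#' @export
sigma_sweep <- function(pair, geometry, pixel_size_um, sigma_list,
                        n_lines = 5L) {
  if (is.unsorted(sigma_list))
    hilo_abort("sigma_list must be ascending", "parameter")
  meas <- lapply(sigma_list, function(s) {
    res <- hilo(pair, sigma = s)
    section_thickness(res$hilo, geometry, pixel_size_um, n_lines)
  })
  df <- data.frame(
    sigma = sigma_list,
    mean_thickness_um = vapply(meas, `[[`, numeric(1), "mean_thickness_um"),
    sd_thickness_um = vapply(meas, `[[`, numeric(1), "sd_thickness_um"))
  attr(df, "measurements") <- meas
  class(df) <- c("sigma_sweep", "data.frame")
  df
}

#' @export
plot.sigma_sweep <- function(x, ...) {
  graphics::plot(x$sigma, x$mean_thickness_um, type = "b", pch = 19,
                 xlab = expression(sigma),
                 ylab = "section thickness (um)", ...)
  graphics::arrows(x$sigma, x$mean_thickness_um - x$sd_thickness_um,
                   x$sigma, x$mean_thickness_um + x$sd_thickness_um,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Peak-to-background contrast along a vertical line profile
#'
#' Maximum divided by minimum of a one-pixel vertical line profile; the
#' minimum is the out-of-focus background. Subtract any camera offset
#' first -- a non-positive minimum leaves the ratio undefined.
#'
#' @param image 2-D raster.
#' @param column column index of the line.
#' @param rows row range of the line (default: all rows).
#' @return positive scalar `max / min`.
#' @export
contrast_ratio <- function(image, column, rows = seq_len(nrow(image))) {
  check_matrix(image)
  if (column < 1 || column > ncol(image) ||
      any(rows < 1) || any(rows > nrow(image)))
    hilo_abort("line segment outside the image", "parameter")
  prof <- image[rows, column]
  if (min(prof) <= 0)
    hilo_abort("profile minimum <= 0: contrast undefined (subtract the camera offset or clamp)",
               "undefined_contrast")
  max(prof) / min(prof)
}

#' Detect speckle-leakage artifacts in a reconstruction
#'
#' When the contrast-evaluation window holds too few speckle grains, the
#' weighting function follows the speckle pattern and illumination
#' structure leaks into the final image. The score is the Pearson
#' correlation between the reconstruction and the illumination pattern
#' after both are high-pass filtered at the grain frequency (1/grain_px).
#' The warning fires when the score exceeds 0.2 or when the window holds
#' fewer than ~3 grains per side.
#'
#' @param hilo_image reconstructed image.
#' @param speckle_pattern the illumination pattern used.
#' @param window_side contrast window side used in the reconstruction.
#' @param grain_px imaged speckle grain size, from [estimate_grain_size()]
#'   or a user hint.
#' @return list with `score`, `warning` (flag) and `reasons`.
#' @export
speckle_leakage <- function(hilo_image, speckle_pattern, window_side,
                            grain_px) {
  check_matrix(hilo_image); check_matrix(speckle_pattern)
  check_same_dim(hilo_image, speckle_pattern)
  kc <- min(1 / grain_px, 0.45)
  grid <- frequency_grid(nrow(hilo_image), ncol(hilo_image))
  hp <- gaussian_highpass(grid, kc)
  a <- as.vector(apply_filter(hilo_image, hp))
  b <- as.vector(apply_filter(speckle_pattern, hp))
  score <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0
           else stats::cor(a, b)
  reasons <- character()
  if (is.finite(score) && score > 0.2)
    reasons <- c(reasons, sprintf("speckle correlation %.3f > 0.2", score))
  if (window_side < 3 * grain_px)
    reasons <- c(reasons,
                 sprintf("window %d px < 3 grains (grain %.3g px)",
                         window_side, grain_px))
  list(score = score, warning = length(reasons) > 0, reasons = reasons)
}

#' Write a plain-text/JSON measurement report
#'
#' @param path output JSON path.
#' @param sigma sectioning parameter used.
#' @param thickness optional `section_measurement`.
#' @param contrast optional named list/vector of contrast ratios.
#' @param leakage optional result of [speckle_leakage()].
#' @return the report list, invisibly.
#' @export
write_measurement_report <- function(path, sigma, thickness = NULL,
                                     contrast = NULL, leakage = NULL) {
  rep <- list(sigma = sigma)
  if (!is.null(thickness))
    rep$section_thickness_um <- list(
      mean = thickness$mean_thickness_um,
      sd = thickness$sd_thickness_um,
      per_line_fwhm_px = thickness$per_line_fwhm_px)
  if (!is.null(contrast)) rep$contrast_ratio <- contrast
  if (!is.null(leakage)) rep$speckle_leakage <- leakage
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rep)
}
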