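#' Widefield detection and noise model
#'
#' Gaussian-optics stand-in for a widefield fluorescence detection path:
#' an in-focus lateral PSF of FWHM `lateral_fwhm_um` whose width grows with
#' defocus dz as `lateral_fwhm_um * sqrt(1 + (dz / z_R)^2)` with
#' `z_R = axial_fwhm_um / 2`. With that choice the blurred peak response to
#' a point halves at dz = +/- axial_fwhm_um / 2, i.e. the axial FWHM of the
#' point response equals `axial_fwhm_um`. Defaults emulate a mesoscale
#' system with 0.7 um lateral / 7 um axial resolution sampled at 224 nm
#' pixels (Nyquist for the lateral FWHM).
#'
#' @param lateral_fwhm_um in-focus lateral PSF FWHM, microns.
#' @param axial_fwhm_um axial FWHM of the detection response, microns.
#' @param pixel_size_um pixel pitch, microns.
#' @param photon_scale expected photon counts per intensity unit; 0
#'   disables photon noise.
#' @param read_sd Gaussian read-noise standard deviation (intensity units);
#'   0 disables it.
#' @param offset constant camera offset added to rendered images.
#' @return an object of class `imaging_model`.
#' @export
imaging_model <- function(lateral_fwhm_um = 0.7, axial_fwhm_um = 7,
                          pixel_size_um = 0.224, photon_scale = 0,
                          read_sd = 0, offset = 0) {
  if (lateral_fwhm_um <= 0 || axial_fwhm_um <= 0 || pixel_size_um <= 0)
    hilo_abort("all widths must be positive", "parameter")
  structure(list(lateral_fwhm_um = lateral_fwhm_um,
                 axial_fwhm_um = axial_fwhm_um,
                 pixel_size_um = pixel_size_um,
                 photon_scale = photon_scale,
                 read_sd = read_sd, offset = offset),
            class = "imaging_model")
}

#' Tilted-layer geometry
#'
#' A thin fluorescent layer tilted by wedging one end of its slide upward:
#' a known height difference over a known base length converts lateral
#' position to axial position, so a lateral FWHM measured in the image can
#' be translated into an axial FWHM.
#'
#' @param height_difference_um height difference between slide ends, microns.
#' @param base_length_um slide base length, microns.
#' @param focus_column image column where the layer crosses the focal plane.
#' @return an object of class `tilt_geometry` with the derived `slope`
#'   (axial microns per lateral micron).
#' @export
tilt_geometry <- function(height_difference_um, base_length_um,
                          focus_column = NULL) {
  if (base_length_um <= 0)
    hilo_abort("base_length_um must be positive", "parameter")
  if (height_difference_um < 0)
    hilo_abort("height_difference_um must be non-negative", "parameter")
  if (height_difference_um >= base_length_um)
    hilo_abort("tilt violates the small-angle regime", "parameter")
  structure(list(height_difference_um = height_difference_um,
                 base_length_um = base_length_um,
                 focus_column = focus_column,
                 slope = height_difference_um / base_length_um),
            class = "tilt_geometry")
}

new_specimen3d <- function(density, z_um, voxel_size_um) {
  structure(list(density = density, z_um = z_um,
                 voxel_size_um = voxel_size_um),
            class = "specimen3d")
}

#' @export
print.specimen3d <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("<specimen3d> %d z-slices of %d x %d px, z in [%.3g, %.3g] um\n",
              d[3], d[1], d[2], min(x$z_um), max(x$z_um)))
  invisible(x)
}

#' Thin tilted fluorescent layer phantom
#'
#' For every image column x the layer's axial centre is
#' `z(x) = (x - focus_column) * pixel_size_um * slope`; the density is a
#' Gaussian axial profile of FWHM `layer_thickness_um` about that centre,
#' uniform along rows, with the per-column integrated density normalized to
#' one (conservation across columns by construction). The layer must be
#' much thinner than the axial response so the measured strip width
#' reflects the system, not the layer.
#'
#' @param geometry a [tilt_geometry()]; `focus_column` defaults to the
#'   image centre.
#' @param layer_thickness_um layer FWHM, microns; must be below
#'   `axial_fwhm_um / 3`.
#' @param fov_shape integer vector `c(n_rows, n_cols)`.
#' @param model an [imaging_model()].
#' @param z_step_um axial sampling step; defaults to half the layer
#'   thickness (capped at 0.5 um).
#' @param z_range_um optional `c(zmin, zmax)`; defaults to the layer's
#'   span plus a 3-thickness margin.
#' @return a `specimen3d`.
#' @export
tilted_layer_phantom <- function(geometry, layer_thickness_um, fov_shape,
                                 model, z_step_um = NULL,
                                 z_range_um = NULL) {
  if (!inherits(geometry, "tilt_geometry"))
    hilo_abort("`geometry` must be tilt_geometry()", "type")
  if (!inherits(model, "imaging_model"))
    hilo_abort("`model` must be imaging_model()", "type")
  if (layer_thickness_um >= model$axial_fwhm_um / 3)
    hilo_abort("layer too thick: thin-layer condition requires thickness < axial FWHM / 3",
               "parameter")
  nr <- fov_shape[1]; nc <- fov_shape[2]
  fc <- if (is.null(geometry$focus_column)) (nc + 1) / 2
        else geometry$focus_column
  zc <- (seq_len(nc) - fc) * model$pixel_size_um * geometry$slope
  if (is.null(z_step_um))
    z_step_um <- min(layer_thickness_um / 2, 0.5)
  if (is.null(z_range_um))
    z_range_um <- range(zc) + c(-3, 3) * layer_thickness_um
  z <- seq(z_range_um[1], z_range_um[2], by = z_step_um)
  if (min(zc) < z_range_um[1] || max(zc) > z_range_um[2])
    hilo_abort("tilt carries the layer outside the simulated z-range",
               "geometry")
  sd_z <- layer_thickness_um / (2 * sqrt(2 * log(2)))
  # per-column axial profile, normalized so each column integrates to 1
  prof <- outer(z, zc, function(zz, cc) exp(-(zz - cc)^2 / (2 * sd_z^2)))
  prof <- sweep(prof, 2, colSums(prof), "/")
  density <- array(0, c(nr, nc, length(z)))
  for (k in seq_along(z))
    density[, , k] <- matrix(prof[k, ], nr, nc, byrow = TRUE)
  new_specimen3d(density, z,
                 c(z_step_um, model$pixel_size_um, model$pixel_size_um))
}

#' Two-plane phantom for contrast-improvement measurements
#'
#' An in-focus plane at z = 0 carrying isolated bright horizontal bands on
#' a dark background (so a vertical line profile has a clean peak and a
#' background minimum) plus a laterally uniform out-of-focus plane at
#' z = `separation_um` that contributes defocused background.
#'
#' @param separation_um axial separation of the two planes; must exceed the
#'   axial FWHM.
#' @param fov_shape integer vector `c(n_rows, n_cols)`.
#' @param model an [imaging_model()].
#' @param band_period_px,band_width_px row period and width of the bright
#'   bands on the in-focus plane.
#' @param background_density density of the out-of-focus plane relative to
#'   the band amplitude.
#' @param infocus_background uniform in-focus background density relative
#'   to the band amplitude (real specimens fluoresce weakly everywhere; a
#'   zero in-focus background leaves the peak-to-background contrast of a
#'   sectioned image undefined, since perfect rejection drives the profile
#'   minimum to zero).
#' @return a `specimen3d`.
#' @export
bilayer_phantom <- function(separation_um, fov_shape, model,
                            band_period_px = 64L, band_width_px = 8L,
                            background_density = 0.5,
                            infocus_background = 0.2) {
  if (!inherits(model, "imaging_model"))
    hilo_abort("`model` must be imaging_model()", "type")
  if (separation_um <= model$axial_fwhm_um)
    hilo_abort("plane separation must exceed the axial FWHM", "parameter")
  nr <- fov_shape[1]; nc <- fov_shape[2]
  rows <- seq_len(nr)
  in_band <- ((rows - 1L) %% band_period_px) < band_width_px
  plane1 <- matrix(as.numeric(in_band) + infocus_background, nr, nc)
  plane2 <- matrix(background_density, nr, nc)
  density <- array(0, c(nr, nc, 2))
  density[, , 1] <- plane1
  density[, , 2] <- plane2
  new_specimen3d(density, c(0, separation_um),
                 c(separation_um, model$pixel_size_um, model$pixel_size_um))
}
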