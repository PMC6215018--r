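fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Gaussian defocus blur sd in pixels at axial offset dz (microns).
defocus_sd_px <- function(model, dz) {
  zr <- model$axial_fwhm_um / 2
  fwhm <- model$lateral_fwhm_um * sqrt(1 + (dz / zr)^2)
  fwhm_to_sd(fwhm) / model$pixel_size_um
}

#' Render a widefield fluorescence image of a 3-D specimen
#'
#' Per z-slice the emission is density times the (z-invariant) illumination
#' pattern; each slice is blurred by a Gaussian PSF whose width grows with
#' defocus (see [imaging_model()]) and the slices are summed -- widefield
#' detection has no axial rejection, so total energy is conserved. The
#' camera offset is added, then photon noise (Poisson below 20 expected
#' counts, a matched-variance Gaussian above) and Gaussian read noise,
#' both seeded. Blurring uses the analytic Gaussian transfer function and
#' periodic FFT convolution; slice spectra are accumulated and inverted
#' once.
#'
#' @param specimen a `specimen3d`.
#' @param model an [imaging_model()].
#' @param focus_z_um focal-plane position, microns.
#' @param illumination 2-D illumination raster matching the lateral shape;
#'   defaults to flat illumination.
#' @param seed seed for the noise draws (only used when noise is on).
#' @return a non-negative matrix.
#' @export
render_widefield <- function(specimen, model, focus_z_um = 0,
                             illumination = NULL, seed = 1L) {
  if (!inherits(specimen, "specimen3d"))
    hilo_abort("`specimen` must be a specimen3d", "type")
  if (!inherits(model, "imaging_model"))
    hilo_abort("`model` must be imaging_model()", "type")
  d <- dim(specimen$density)
  if (is.null(illumination))
    illumination <- matrix(1, d[1], d[2])
  check_matrix(illumination)
  if (!identical(dim(illumination), d[1:2]))
    hilo_abort("illumination shape does not match specimen slices", "shape")
  grid <- frequency_grid(d[1], d[2])
  k2 <- grid$radial^2
  acc <- matrix(0 + 0i, d[1], d[2])
  for (k in seq_len(d[3])) {
    slice <- specimen$density[, , k]
    if (!any(slice != 0)) next
    s_px <- defocus_sd_px(model, specimen$z_um[k] - focus_z_um)
    otf <- exp(-2 * pi^2 * s_px^2 * k2)
    acc <- acc + stats::fft(slice * illumination) * otf
  }
  img <- Re(stats::fft(acc, inverse = TRUE)) / length(acc)
  img <- pmax(img, 0) + model$offset
  add_camera_noise(img, model, seed)
}

# Photon + read noise. Poisson exactly below 20 expected counts, Gaussian
# with matching variance above (speed with the correct variance structure).
add_camera_noise <- function(img, model, seed) {
  if (model$photon_scale <= 0 && model$read_sd <= 0) return(img)
  with_seed(seed, {
    out <- img
    if (model$photon_scale > 0) {
      counts <- img * model$photon_scale
      noisy <- counts
      lo <- counts < 20
      if (any(lo)) noisy[lo] <- stats::rpois(sum(lo), counts[lo])
      if (any(!lo))
        noisy[!lo] <- counts[!lo] +
          sqrt(counts[!lo]) * stats::rnorm(sum(!lo))
      out <- noisy / model$photon_scale
    }
    if (model$read_sd > 0)
      out <- out + stats::rnorm(length(out), sd = model$read_sd)
    matrix(pmax(out, 0), nrow(img), ncol(img))
  })
}

#' Render a co-registered uniform/speckle image pair of a specimen
#'
#' The speckle member uses one frozen speckle pattern; the uniform member
#' uses [uniform_illumination()] with `n_uniform` averaged realizations.
#' Both members share the specimen, focus and noise model; the speckle
#' pattern, diffuser average and the two noise draws use decorrelated
#' streams derived from `seed`.
#'
#' @param specimen a `specimen3d`.
#' @param model an [imaging_model()].
#' @param focus_z_um focal-plane position, microns.
#' @param speckle a [speckle_params()].
#' @param n_uniform realizations averaged for the uniform member.
#' @param seed master seed.
#' @return an [image_pair()].
#' @export
render_pair <- function(specimen, model, focus_z_um = 0,
                        speckle = speckle_params(), n_uniform = 100L,
                        seed = 1L) {
  d <- dim(specimen$density)
  sp <- speckle
  sp$seed <- derive_seed(seed, 101L)
  ill_s <- generate_speckle(d[1:2], sp)
  su <- speckle
  su$seed <- derive_seed(seed, 202L)
  ill_u <- uniform_illumination(d[1:2], su, n_uniform)
  img_u <- render_widefield(specimen, model, focus_z_um, ill_u,
                            seed = derive_seed(seed, 303L))
  img_s <- render_widefield(specimen, model, focus_z_um, ill_s,
                            seed = derive_seed(seed, 404L))
  image_pair(img_u, img_s, pixel_size_um = model$pixel_size_um)
}
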