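# Shared fixtures, built in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A smooth positive test image with content across the spectrum.
smooth_image <- function(nr, nc, seed = 42, corr = 0.05) {
  g <- frequency_grid(nr, nc)
  set.seed(seed)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  lp <- exp(-g$radial^2 / (2 * corr^2))
  s <- Re(stats::fft(stats::fft(z) * lp, inverse = TRUE)) / (nr * nc)
  s - min(s) + 0.5
}

# Small noiseless tilted-layer scene used across characterization tests:
# 256 rows x 1024 cols, layer spanning +/-30 um axially.
small_tilt_fixture <- function() {
  fixture("small_tilt", function() {
    model <- imaging_model(photon_scale = 500, read_sd = 0.02,
                           offset = 0.1)
    geom <- tilt_geometry(60, 1024 * model$pixel_size_um)
    spec <- tilted_layer_phantom(geom, 1, c(256, 1024), model)
    pair <- render_pair(spec, model, 0,
                        speckle_params(grain_px = 3, seed = 5),
                        n_uniform = 50, seed = 11)
    list(model = model, geom = geom, pair = pair)
  })
}

# Full-scale tilted-layer scene matching the study conditions: 0.7 um
# lateral / 7 um axial FWHM at 0.224 um pixels, thin (1 um) layer spanning
# +/-30 um axially across 2048 columns, speckle grain ~3 px, fixed seeds.
full_tilt_fixture <- function() {
  fixture("full_tilt", function() {
    model <- imaging_model(photon_scale = 500, read_sd = 0.02,
                           offset = 0.1)
    geom <- tilt_geometry(60, 2048 * model$pixel_size_um)
    spec <- tilted_layer_phantom(geom, 1, c(512, 2048), model)
    pair <- render_pair(spec, model, 0,
                        speckle_params(grain_px = 3, seed = 5),
                        n_uniform = 100, seed = 11)
    list(model = model, geom = geom, pair = pair)
  })
}

# Bilayer scene for contrast-improvement tests.
bilayer_fixture <- function() {
  fixture("bilayer", function() {
    model <- imaging_model(photon_scale = 2000, read_sd = 0.005,
                           offset = 0.05)
    spec <- bilayer_phantom(21, c(256, 256), model)
    pair <- render_pair(spec, model, 0,
                        speckle_params(grain_px = 3, seed = 7),
                        n_uniform = 50, seed = 23)
    list(model = model, spec = spec, pair = pair)
  })
}
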