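test_that("tilted-layer phantom geometry follows the tilt", {
  model <- imaging_model()
  # zero tilt: layer flat at z = 0 in every column
  flat <- tilted_layer_phantom(tilt_geometry(0, 75000), 1, c(16, 64), model)
  centre <- apply(flat$density[1, , ], 1,
                  function(p) sum(flat$z_um * p) / sum(p))
  expect_equal(centre, rep(0, 64), tolerance = 1e-9)
  # 1 mm shim under a 75 mm slide: z advances 100 * 0.224 / 75 um
  # per 100 columns
  geom <- tilt_geometry(1000, 75000)
  ph <- tilted_layer_phantom(geom, 1, c(16, 256), model)
  centre <- apply(ph$density[1, , ], 1,
                  function(p) sum(ph$z_um * p) / sum(p))
  expect_equal(centre[201] - centre[101], 100 * 0.224 / 75,
               tolerance = 1e-4)
  # per-column integrated density is constant by construction
  colsum <- apply(ph$density, 2, sum)
  expect_equal(colsum, rep(colsum[1], 256), tolerance = 1e-12)
  expect_error(tilted_layer_phantom(geom, 3, c(16, 64), model),
               class = "hilosect_parameter")
  expect_error(tilted_layer_phantom(tilt_geometry(10, 64 * 0.224), 1,
                                    c(16, 64), model,
                                    z_range_um = c(-1, 1)),
               class = "hilosect_geometry")
})

test_that("widefield render blurs with the in-focus PSF and conserves energy", {
  model <- imaging_model()   # noise off
  n <- 64
  density <- array(0, c(n, n, 1))
  density[n / 2, n / 2, 1] <- 1
  spec <- structure(list(density = density, z_um = 0,
                         voxel_size_um = c(1, 0.224, 0.224)),
                    class = "specimen3d")
  img <- render_widefield(spec, model, 0)
  # closed-form sampled Gaussian of the in-focus PSF
  s_px <- (0.7 / (2 * sqrt(2 * log(2)))) / 0.224
  xy <- seq_len(n) - n / 2
  ref <- outer(xy, xy, function(a, b)
    exp(-(a^2 + b^2) / (2 * s_px^2)) / (2 * pi * s_px^2))
  # absolute comparison: the discrete OTF leaves a ~1e-7 ringing floor
  # where the analytic Gaussian is effectively zero
  expect_lt(max(abs(img - ref)), 1e-4 * max(ref))
  expect_equal(sum(img), sum(density), tolerance = 0.02)
})

test_that("imaged speckle contrast decays monotonically with defocus", {
  model <- imaging_model()
  n <- 128
  density <- array(1, c(n, n, 1))
  ill <- generate_speckle(c(n, n), speckle_params(grain_px = 4, seed = 3))
  dz <- seq(0, 3 * model$axial_fwhm_um, length.out = 7)
  contrast <- vapply(dz, function(d) {
    spec <- structure(list(density = density, z_um = d,
                           voxel_size_um = c(1, 0.224, 0.224)),
                      class = "specimen3d")
    img <- render_widefield(spec, model, 0, ill)
    core <- img[33:96, 33:96]
    sd(core) / mean(core)
  }, numeric(1))
  expect_true(all(diff(contrast) < 0))
})

test_that("bilayer phantom produces defocused background between bands", {
  model <- imaging_model()
  spec <- bilayer_phantom(21, c(128, 128), model)
  img <- render_widefield(spec, model, 0)
  between <- img[((seq_len(128) - 1) %% 64) == 36, ]
  expect_gt(min(between), 0.1)   # defocused plane fills the gaps
  spec0 <- bilayer_phantom(21, c(128, 128), model, background_density = 0,
                           infocus_background = 0)
  img0 <- render_widefield(spec0, model, 0)
  between0 <- img0[((seq_len(128) - 1) %% 64) == 36, ]
  expect_lt(max(between0), 1e-3)
  expect_error(bilayer_phantom(5, c(128, 128), model),
               class = "hilosect_parameter")
})

test_that("rendered pairs are reproducible and bias-free", {
  model <- imaging_model()   # noise off
  spec <- bilayer_phantom(21, c(96, 96), model)
  sp <- speckle_params(grain_px = 3, seed = 4)
  p1 <- render_pair(spec, model, 0, sp, n_uniform = 20, seed = 99)
  p2 <- render_pair(spec, model, 0, sp, n_uniform = 20, seed = 99)
  expect_identical(p1$uniform, p2$uniform)
  expect_identical(p1$speckle, p2$speckle)
  # difference image has near-zero mean relative to the uniform image
  idm <- mean(difference_image(p1))
  expect_lt(abs(idm), 0.02 * mean(p1$uniform))
  # zero modulation: members identical when noise is off
  p0 <- render_pair(spec, model, 0,
                    speckle_params(grain_px = 3, modulation = 0, seed = 4),
                    n_uniform = 5, seed = 99)
  expect_equal(p0$uniform, p0$speckle, tolerance = 1e-12)
})
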