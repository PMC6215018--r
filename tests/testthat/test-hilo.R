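test_that("parameter resolution follows the sigma calibration", {
  p1 <- hilo_params(1)
  expect_equal(p1$sigma_bp, 0.1)
  expect_equal(p1$k_c, 0.018)
  expect_identical(p1$window_side, 27L)   # nearest odd to 27.78
  p2 <- hilo_params(2)
  expect_equal(p2$sigma_bp, 0.2)
  expect_equal(p2$k_c, 0.036)
  expect_identical(p2$window_side, 13L)   # nearest odd to 13.89
  expect_equal(p2$k_c, 0.18 * p2$sigma_bp, tolerance = 1e-12)
  expect_error(hilo_params(0.5), class = "hilosect_below_calibration")
  # overrides replace individual fields after validation
  p3 <- hilo_params(1, window_side = 61)
  expect_identical(p3$window_side, 61L)
  expect_error(hilo_params(1, window_side = 10),
               class = "hilosect_parameter")
})

test_that("difference image retains signed values", {
  iu <- matrix(c(1, 3, 2, 4), 2, 2)   # [[1,2],[3,4]] in row-major reading
  is_ <- matrix(2, 2, 2)
  pair <- image_pair(iu, is_)
  expect_identical(difference_image(pair),
                   matrix(c(1, -1, 0, -2), 2, 2))
  pair2 <- image_pair(iu, 2 * iu)
  expect_identical(difference_image(pair2), iu)
  expect_error(image_pair(iu, matrix(1, 3, 3)), class = "hilosect_shape")
})

test_that("local contrast matches a brute-force sliding window", {
  set.seed(4)
  nr <- 24; nc <- 30; w <- 5L
  d <- matrix(rnorm(nr * nc), nr, nc)
  u <- matrix(runif(nr * nc, 0.5, 2), nr, nc)
  got <- local_contrast(d, u, w)$values
  # independent oracle: explicit symmetric (edge-duplicating) mirror
  # indexing and per-pixel loops
  mirror <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  h <- (w - 1) / 2
  want <- matrix(0, nr, nc)
  for (r in 1:nr) for (cc in 1:nc) {
    ri <- mirror((r - h):(r + h), nr); ci <- mirror((cc - h):(cc + h), nc)
    win_d <- d[ri, ci]; win_u <- u[ri, ci]
    sd_pop <- sqrt(mean(win_d^2) - mean(win_d)^2)
    want[r, cc] <- sd_pop / mean(win_u)
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("local contrast is scale invariant and zero for flat difference", {
  u <- matrix(2, 32, 32)
  expect_true(all(local_contrast(matrix(0, 32, 32), u, 5)$values == 0))
  set.seed(5)
  d <- matrix(rnorm(32 * 32), 32, 32)
  u2 <- matrix(runif(32 * 32, 1, 2), 32, 32)
  c1 <- local_contrast(d, u2, 7)$values
  c2 <- local_contrast(2 * d, 2 * u2, 7)$values
  expect_equal(c1, c2, tolerance = 1e-12)
  expect_error(local_contrast(d, u2, 6), class = "hilosect_parameter")
  expect_error(local_contrast(d, u2, 33), class = "hilosect_configuration")
})

test_that("weighted uniform image is the elementwise product", {
  iu <- matrix(c(2, 4), 1, 2)
  expect_error(weighted_uniform(iu, matrix(1, 2, 2)))
  iu <- rbind(c(2, 4), c(1, 1))
  cm <- rbind(c(0.5, 0.25), c(1, 0))
  expect_identical(weighted_uniform(iu, cm), iu * cm)
  expect_identical(weighted_uniform(iu, matrix(0, 2, 2)),
                   matrix(0, 2, 2))
})

test_that("eta is the annulus spectral ratio with a degenerate fallback", {
  img <- smooth_image(96, 96, seed = 3, corr = 0.1)
  e <- compute_eta(img, img, 0.05)
  expect_equal(e$eta, 1, tolerance = 1e-12)
  expect_false(e$degenerate)
  e2 <- compute_eta(img, img / 4, 0.05)
  expect_equal(e2$eta, 4, tolerance = 1e-10)
  e3 <- compute_eta(img, matrix(0, 96, 96), 0.05)
  expect_true(e3$degenerate)
  expect_equal(e3$eta, 1)
})

test_that("identical inputs collapse the reconstruction to a pure high-pass", {
  iu <- smooth_image(128, 128, seed = 21)
  pair <- image_pair(iu, iu)
  res <- hilo(pair, sigma = 2)
  hp <- gaussian_highpass(frequency_grid(128, 128), res$params$k_c)
  ref <- apply_filter(iu, hp)
  expect_lt(max(abs(res$hilo - ref)) / max(abs(ref)), 1e-8)
  expect_length(res$warnings, 1)
})

test_that("the reconstruction is homogeneous of degree one", {
  fx <- small_tilt_fixture()
  pair <- fx$pair
  small <- image_pair(pair$uniform[1:256, 1:256],
                      pair$speckle[1:256, 1:256])
  r1 <- hilo(small, sigma = 2)
  c_ <- 3.7
  r2 <- hilo(image_pair(c_ * small$uniform, c_ * small$speckle), sigma = 2)
  expect_equal(r2$eta, r1$eta, tolerance = 1e-9)
  expect_equal(r2$hilo, c_ * r1$hilo, tolerance = 1e-6)
})

test_that("the stored result obeys the fusion identity bin for bin", {
  fx <- bilayer_fixture()
  res <- hilo(fx$pair, sigma = 2)
  expect_identical(res$unclamped,
                   res$highpassed_uniform + res$eta * res$lofreq)
  # clamping only affects the final image
  p <- hilo_params(2, clamp_negative = TRUE)
  resc <- hilo(fx$pair, params = p)
  expect_true(all(resc$hilo >= 0))
  expect_identical(resc$hilo, pmax(resc$unclamped, 0))
})

test_that("the reconstruction is shift equivariant away from boundaries", {
  iu <- smooth_image(192, 192, seed = 31, corr = 0.08)
  set.seed(77)
  sp <- generate_speckle(c(192, 192), speckle_params(grain_px = 4, seed = 8))
  is_ <- iu * sp
  shift <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    m[((seq_len(nr) - 1 - dr) %% nr) + 1, ((seq_len(nc) - 1 - dc) %% nc) + 1]
  }
  dr <- 7; dc <- 5
  r0 <- hilo(image_pair(iu, is_), sigma = 2)
  # eta is a global spectral estimate whose annulus content changes with
  # the frame-edge window padding; hold it fixed to test the pipeline
  p_fix <- hilo_params(2, eta = r0$eta)
  r1 <- hilo(image_pair(shift(iu, dr, dc), shift(is_, dr, dc)),
             params = p_fix)
  p <- r0$params
  margin <- p$window_side + ceiling(3 / (2 * pi * p$k_c)) + max(dr, dc)
  core_r <- (margin + 1):(192 - margin)
  core_c <- (margin + 1):(192 - margin)
  a <- shift(r0$hilo, dr, dc)[core_r, core_c]
  b <- r1$hilo[core_r, core_c]
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-2)
})

test_that("out-of-focus structure is suppressed relative to widefield", {
  fx <- bilayer_fixture()
  res <- hilo(fx$pair, sigma = 2)
  iu <- fx$pair$uniform
  # in-focus rows are the band centres; out-of-focus proxy rows lie between
  rows_in <- which(((seq_len(256) - 1) %% 64) == 4)
  rows_out <- which(((seq_len(256) - 1) %% 64) == 36)
  off <- fx$model$offset
  ratio_wf <- mean(iu[rows_out, ] - off) / mean(iu[rows_in, ] - off)
  hil <- pmax(res$hilo, 0)
  ratio_hilo <- mean(hil[rows_out, ]) / mean(hil[rows_in, ])
  expect_lt(ratio_hilo, ratio_wf)
})
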