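test_that("frequency grid matches the discrete Fourier frequencies", {
  g <- frequency_grid(8, 8)
  expect_identical(g$radial[1, 1], 0)
  # Nyquist corner of an even 8x8 grid sits at bin (5, 5)
  expect_equal(g$radial[5, 5], sqrt(0.5^2 + 0.5^2))
  g2 <- frequency_grid(16, 8)
  expect_equal(g2$radial[9, 1], 0.5)   # row-Nyquist, zero column frequency
  expect_true(max(g$radial) <= sqrt(2) * 0.5 + 1e-15)
  # reproducible
  expect_identical(frequency_grid(16, 8)$radial, g2$radial)
  expect_error(frequency_grid(4, 16), class = "hilosect_size")
})

test_that("gaussian high-pass has half gain at the cut-off", {
  g <- frequency_grid(100, 100)
  kc <- 0.1
  hp <- gaussian_highpass(g, kc)
  expect_equal(hp$gains[1, 1], 0)
  # bin (1, 11) has |k| = 10/100 = kc exactly
  expect_equal(hp$gains[1, 11], 0.5, tolerance = 1e-12)
  # closed form at 2 kc: exponent is log(2) (k/kc)^2
  expect_equal(hp$gains[1, 21], 1 - 2^-4, tolerance = 1e-12)
  expect_true(all(hp$gains >= 0 & hp$gains <= 1))
  # monotone in |k| along the frequency axis
  expect_true(all(diff(hp$gains[1, 1:51]) >= 0))
  expect_error(gaussian_highpass(g, 0.6), class = "hilosect_parameter")
  expect_error(gaussian_highpass(g, 0), class = "hilosect_parameter")
})

test_that("low-pass complement satisfies LP + HP = 1 exactly", {
  g <- frequency_grid(64, 48)
  hp <- gaussian_highpass(g, 0.07)
  lp <- lowpass_complement(hp)
  expect_identical(lp$gains + hp$gains, matrix(1, 64, 48))
  expect_equal(lp$gains[1, 1], 1)
  g2 <- frequency_grid(100, 100)
  lp2 <- lowpass_complement(gaussian_highpass(g2, 0.1))
  expect_equal(lp2$gains[1, 21], 2^-4, tolerance = 1e-12)
  expect_error(lowpass_complement(lp), class = "hilosect_type")
})

test_that("bandpass is a difference of Gaussians with peak 1/4 at 2 sigma sqrt(log 2)", {
  # dense 1-D oracle for the radial profile
  sig <- 0.08
  k <- seq(0, 0.7, by = 1e-5)
  prof <- exp(-k^2 / (4 * sig^2)) - exp(-k^2 / (2 * sig^2))
  expect_equal(max(prof), 0.25, tolerance = 1e-9)
  expect_equal(k[which.max(prof)], 2 * sig * sqrt(log(2)), tolerance = 1e-4)

  g <- frequency_grid(128, 128)
  bp <- bandpass_filter(g, sig)
  expect_equal(bp$gains[1, 1], 0)
  expect_true(all(bp$gains >= 0))
  expect_true(max(bp$gains) <= 0.25 + 1e-12)
  # grid maximum agrees with the dense oracle within one grid bin
  kmax_grid <- g$radial[which.max(bp$gains)]
  expect_lt(abs(kmax_grid - 2 * sig * sqrt(log(2))), 1 / 128)
  # direct evaluation at k = 2 sigma
  i <- which(abs(g$radial[1, ] - 2 * sig) < 1e-9)[1]
  if (!is.na(i))
    expect_equal(bp$gains[1, i], exp(-1) - exp(-2), tolerance = 1e-12)
  expect_error(bandpass_filter(g, 0), class = "hilosect_parameter")
  expect_error(bandpass_filter(g, -1), class = "hilosect_parameter")
  # above Nyquist the profile is still well defined (flattened)
  expect_no_error(bandpass_filter(g, 0.6))
})

test_that("apply_filter scales pure frequencies by the filter gain", {
  n <- 64
  g <- frequency_grid(n, n)
  hp <- gaussian_highpass(g, 0.1)
  lp <- lowpass_complement(hp)
  # constant image: DC only
  const <- matrix(3.2, n, n)
  expect_lt(max(abs(apply_filter(const, hp))), 1e-10)
  expect_equal(apply_filter(const, lp), const, tolerance = 1e-12)
  # eigenfunction: cosine at k0 = 8/64 cycles/pixel along columns
  k0 <- 8 / n
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  cosine <- cos(2 * pi * k0 * x)
  gain <- hp$gains[1, 9]
  expect_equal(apply_filter(cosine, hp), gain * cosine, tolerance = 1e-6)
  expect_error(apply_filter(matrix(1, 32, 32), hp),
               class = "hilosect_shape")
  bad <- matrix(1, n, n); bad[3, 3] <- NA
  expect_error(apply_filter(bad, hp), class = "hilosect_data")
})

test_that("filtering is linear", {
  set.seed(9)
  n <- 64
  g <- frequency_grid(n, n)
  bp <- bandpass_filter(g, 0.1)
  x <- matrix(rnorm(n^2), n, n)
  y <- matrix(rnorm(n^2), n, n)
  a <- 2.5; b <- -0.7
  lhs <- apply_filter(a * x + b * y, bp)
  rhs <- a * apply_filter(x, bp) + b * apply_filter(y, bp)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})
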