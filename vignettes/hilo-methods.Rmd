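---
title: "HiLo optical sectioning: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HiLo optical sectioning: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hilosect)
```

This vignette records the mathematical model implemented by `hilosect`,
the numerical conventions chosen where the method leaves freedom, and the
scope and known limits of the bundled simulator. It is the reference for
anyone auditing the package's results.

## 1. The reconstruction model

HiLo fuses two raw widefield images of the same field: `i_u` under
uniform illumination and `i_s` under a stationary laser speckle pattern.
All processing is linear filtering plus one local nonlinearity (the
contrast map).

**High-frequency leg.** High spatial frequencies only transfer near
focus, so the high-pass of the uniform image is already sectioned:

    i_HP = F^-1[ HP(k) . F(i_u) ],   HP(k) = 1 - exp(-k^2 / (2 s^2))

with `s` chosen so that `HP(k_c) = 1/2`, i.e. `s = k_c / sqrt(2 ln 2)`.

**Low-frequency leg.** Low frequencies are recovered from the speckle
modulation. The difference image `i_d = i_s - i_u` cancels specimen
structure (signed values are kept). It is band-pass filtered by a
difference of Gaussians

    BP(k) = exp(-k^2 / (4 sigma_bp^2)) - exp(-k^2 / (2 sigma_bp^2)),

which is zero at DC and peaks (value 1/4) at `k = 2 sigma_bp sqrt(ln 2)`.
A sliding-window contrast map `C = sd / mean` is evaluated on the
band-passed difference image over square windows of side
`window_side = 1 / (2 k_c)` pixels; the in-focus weight multiplies the
uniform image, `i_su = i_u . C`, and the Lo leg is its low-pass,
`i_LP = F^-1[ (1 - HP) . F(i_su) ]`.

**Fusion.** `i_HiLo = i_HP + eta . i_LP`, where `eta` matches the
spectral amplitudes of the two legs at the crossover `k_c` so the seam is
continuous. The stored result keeps every intermediate and satisfies the
identity `hilo = highpassed_uniform + eta * lofreq` bin for bin.

## 2. Parameter calibration

One user-facing parameter `sigma >= 1` controls sectioning strength:

| quantity      | rule                          | sigma = 1 | sigma = 2 |
|---------------|-------------------------------|-----------|-----------|
| `sigma_bp`    | `sigma / 10` cycles/pixel     | 0.1       | 0.2       |
| `k_c`         | `0.18 sigma_bp`               | 0.018     | 0.036     |
| `window_side` | `1 / (2 k_c)`, odd-rounded    | 27        | 13        |

`sigma < 1` is rejected (`hilosect_below_calibration`): the calibration
places the linear sectioning regime at `sigma >= 1`. `sigma_bp` above the
Nyquist frequency (0.5 cycles/pixel, reached at `sigma > 5`) is accepted
with a warning — the band-pass then flattens over the representable band
and sectioning saturates. Each derived field of `hilo_params()` can be
overridden; overriding `window_side` upward is the standard remedy when
the imaged speckle grain is coarse (see section 5 on leakage).

## 3. Numerical conventions

Choices the method itself does not pin down, and what this package does:

- **DFT convention.** Unnormalized forward transform, `1/N`-normalized
  inverse (`stats::fft`); filters are pure real gains, so the convention
  cancels in every filtered image.
- **Contrast denominator.** `C = sd / mean` uses the local mean of the
  *uniform* image in the denominator, not of the difference image (whose
  local mean is near zero by construction and would be numerically
  explosive). The standard deviation is the population form, computed
  from running first and second moments. Means are guarded by a floor of
  `1e-6 * mean(i_u)`; windows whose mean falls below it produce zero
  weight rather than infinities.
- **Window padding.** The sliding window uses reflective (symmetric)
  padding, so the contrast map has full support and no wrap-around
  artifacts from bright opposite edges.
- **eta estimation.** The amplitudes `A_HP`, `A_LP` are the mean
  magnitudes of the discrete Fourier transforms of `i_HP` and `i_LP`
  over all bins whose radial frequency lies within half a bin-width
  (`0.5 / min(n_rows, n_cols)`) of `k_c`, excluding DC. A point
  evaluation at a single bin would be noise-dominated; the azimuthal
  annulus is the stable estimator of the radial spectrum. If
  `A_LP` vanishes (e.g. `i_s = i_u`), `eta` falls back to 1 and the
  result carries a degenerate-spectrum note. The estimator is known to
  be biased low on scenes whose spectrum near `k_c` is dominated by
  residual speckle and contrast-map sampling noise rather than
  structure; `hilo_params(eta = ...)` exists for such cases.
- **Odd rounding.** `window_side` rounds to the nearest odd integer
  (27.78 → 27, 13.89 → 13) so the window has a center pixel.
- **Tiled processing.** Tiles are padded by a halo with *periodic* wrap
  at the frame border, matching the full-frame FFT's boundary
  convention; the required halo is `window_side` plus three spatial
  standard deviations of the widest filter kernel. `eta` is computed
  once globally — per-tile values would create tile-to-tile brightness
  steps. Interior pixels agree with the full-frame path to better than
  1e-3 relative.

## 4. The simulator: scope and limits

The bundled simulator is a *detection-side* model, built for testing the
reconstruction and measurement code at desk scale:

- **Speckle synthesis** draws a uniform random phase over a disk-shaped
  pupil support and takes the squared modulus of its transform. The disk
  radius is calibrated (`0.5145 / grain_px` cycles/pixel) so that the
  requested grain equals the autocovariance FWHM measured by
  `estimate_grain_size()`; fully developed patterns have contrast ~1,
  and an `n`-pattern average models the rotating diffuser with contrast
  `~1/sqrt(n)`.
- **Defocus** applies a Gaussian optical transfer function per z-slice
  with lateral width growing as
  `fwhm(dz) = fwhm_0 sqrt(1 + (dz / z_R)^2)`, `z_R` = half the axial
  FWHM; slice spectra are accumulated and inverted once. Energy is
  conserved exactly under the periodic convention.
- **Noise** is Poisson below 20 expected counts and matched-variance
  Gaussian above, plus Gaussian read noise and a constant camera offset.
- **Phantoms**: a tilted thin layer with exact per-column axial
  normalization, and a two-plane ("bilayer") scene whose in-focus plane
  carries bright bands over a weak uniform in-focus background. The
  in-focus background matters: with literally zero in-focus background a
  perfect sectioning algorithm drives the between-band minimum to zero
  and the peak/background contrast metric is undefined by construction.

**Known limit — direction of the thickness-versus-sigma trend.** On
reference hardware, section thickness grows with `sigma` (roughly
6.8 µm at `sigma = 1` to ~10 µm at `sigma = 3` for Mesolens-class
optics). This simulator reproduces the correct *magnitude* (≈ 5–9 µm)
but the opposite *direction*: measured thickness falls as `sigma` rises
(≈ 8.9, 6.2, 5.0 µm at `sigma = 1, 2, 3` on the 512 × 2048 reference
scene). The cause is structural. Here the axial response is set entirely
by the defocus decay of imaged speckle contrast at the band-pass scale:
larger `sigma_bp` selects finer speckle structure, which blurs away
faster with defocus, so the measured section *narrows*. In a physical
system the illumination-side speckle field also decorrelates axially,
and the detected band shifts with `sigma` in a way that *broadens* the
section; that term has no counterpart in a detection-only model. The
simulator's defaults deliberately remain at the study conditions instead
of being adjusted until the trend matches; the discrepancy is asserted
honestly by the acceptance tests and documents the simulator's boundary
of validity.

## 5. Characterization tools

- **Tilted-layer thickness**: Gaussian fits (`A exp(-(x-x0)^2/(2w^2)) + b`,
  bounded Levenberg–Marquardt with retries over width initializations) to
  five one-pixel horizontal profiles drawn from the central 50% of rows;
  lateral FWHM converts to axial microns via the known tilt slope.
- **Contrast ratio**: max/min of a line profile; refuses non-positive
  minima (subtract the camera offset first).
- **Speckle leakage**: when the contrast window holds too few grains the
  weight map follows the illumination and speckle structure leaks into
  the output. The detector correlates reconstruction and pattern after
  high-pass filtering at the grain frequency and warns when the
  correlation exceeds 0.2 or the window holds fewer than ~3 grains per
  side.

## 6. Problem sizes

The package's own test scales, chosen to keep the full suite within a
few minutes of CPU time: property suites run at 256², tiled equivalence
at 512², and the end-to-end sectioning measurement on a 512 × 2048 scene
(the largest size at which the ±30 µm tilt, the 0.224 µm pixel pitch and
a 1 µm layer coexist at study conditions on one desk-scale frame).
Frames too large for one FFT go through `hilo_tiled()`, whose memory use
is bounded by the tile-plus-halo size.
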