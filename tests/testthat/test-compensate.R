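test_that("the digital reference wave is a unit-modulus plane wave", {
  p <- std_params(64)
  r0 <- digital_reference_wave(tilt_angles(0, 0), p)
  expect_equal(r0$values, matrix(1 + 0i, 64, 64))
  rt <- digital_reference_wave(tilt_angles(0.02, -0.013), p)
  expect_equal(Mod(rt$values), matrix(1, 64, 64), tolerance = 1e-12)
})

test_that("tilt compensation cancels a simulated carrier", {
  p <- std_params(256)
  fx <- blob_hologram(p, offset_bins = c(60, 45))
  S <- compute_spectrum(fx$holo)
  roi <- spectrum_roi(128 - 60, 128 - 45, 40, 40)
  ft <- compensate_tilt(filter_plus_one(S, roi), tilt_from_roi(roi, p))
  ph <- Arg(ft$values)
  gx <- wrap_phase(ph[, -1] - ph[, -ncol(ph)])
  gy <- wrap_phase(ph[-1, ] - ph[-nrow(ph), ])
  # residual mean phase gradient below a tenth of a bin
  expect_lt(abs(mean(gx)), 2 * pi / (10 * p$X))
  expect_lt(abs(mean(gy)), 2 * pi / (10 * p$Y))
})

test_that("tilt compensation is an involution and exact on conj(r_D)", {
  p <- std_params(64)
  tilt <- tilt_angles(0.015, -0.01)
  rd <- digital_reference_wave(tilt, p)
  out <- compensate_tilt(complex_field(Conj(rd$values), p), tilt)
  expect_equal(out$values, matrix(1 + 0i, 64, 64), tolerance = 1e-12)
  f <- complex_field(matrix(complex(real = rnorm(64^2),
                                    imaginary = rnorm(64^2)), 64, 64), p)
  back <- compensate_tilt(compensate_tilt(f, tilt),
                          tilt_angles(-tilt$theta_x, -tilt$theta_y))
  expect_equal(back$values, f$values, tolerance = 1e-12)
})

test_that("a non-telecentric field shows rings after tilt compensation", {
  p <- std_params(256)
  C <- 5e4  # >= 3 wraps across the field
  tr <- truth_from_bins(p, offset_bins = c(60, 45), C = C)
  S <- compute_spectrum(simulate_hologram(tr))
  roi <- spectrum_roi(68, 83, 90, 90)
  ft <- compensate_tilt(filter_plus_one(S, roi), tilt_from_roi(roi, p))
  ph <- Arg(ft$values)
  # count sign alternations of the wrapped phase along the centre row
  row <- ph[129, ]
  wraps <- sum(abs(diff(row)) > pi)
  expect_gte(wraps, 3)
})

test_that("the conjugated spherical wave matches its closed form", {
  p <- acq_params(1024, 1024, 5.86, 0.532)
  sp <- spherical_wavefront(2.644e5, 2.644e5, h = 512, g = 512)
  us <- conjugate_spherical_wave(sp, p)
  expect_equal(Mod(us$values), matrix(1, 1024, 1024), tolerance = 1e-12)
  # vertex phase is exactly zero
  expect_equal(Arg(us$values[513, 513]), 0)
  # 100 columns from the centre: -pi*(100*5.86)^2/(0.532*2.644e5)
  want <- -pi * (100 * 5.86)^2 / (0.532 * 2.644e5)
  expect_equal(signif(want, 3), -7.67)
  expect_equal(Arg(us$values[513, 613]), wrap_phase(want), tolerance = 1e-9)
})

test_that("telecentric flag yields the unit spherical factor", {
  p <- std_params(64)
  us <- conjugate_spherical_wave(spherical_wavefront(telecentric = TRUE), p)
  expect_equal(us$values, matrix(1 + 0i, 64, 64))
})

test_that("sphere compensation cancels exactly and flags the wrong sign", {
  p <- std_params(256)
  sp <- spherical_wavefront(5e4, 5e4, h = 120, g = 140, sign = 1)
  us <- conjugate_spherical_wave(sp, p)
  ph0 <- compensate_sphere(complex_field(Conj(us$values), p), sp)
  expect_lt(max(abs(ph0$values)), 1e-9)
  expect_wrapped(ph0)
  # compensating with the flipped sign doubles the ring frequency
  flipped <- spherical_wavefront(5e4, 5e4, h = 120, g = 140, sign = -1)
  ph2 <- compensate_sphere(complex_field(Conj(us$values), p), flipped)
  grad <- function(v) mean(abs(wrap_phase(v[, -1] - v[, -ncol(v)])))
  expect_gt(grad(ph2$values), 10 * grad(ph0$values) + 1e-6)
})

test_that("background SD is small when true parameters are supplied", {
  p <- std_params(256)
  C <- 1.3e5
  tr <- truth_from_bins(p, offset_bins = c(60, 70), C = C,
                        pattern = list(kind = "disc"))
  S <- compute_spectrum(simulate_hologram(tr))
  roi <- spectrum_roi(68, 58, 100, 100)
  ft <- compensate_tilt(filter_plus_one(S, roi, apodize = 0.2),
                        tilt_from_roi(roi, p))
  ph <- compensate_sphere(ft, spherical_wavefront(C, C, h = 128, g = 128))
  bg <- tr$object_phase == 0
  expect_lt(circular_sd(ph$values[bg]), 0.1)
})

test_that("the sphere centre is recovered within two pixels", {
  p <- std_params(256)
  C <- 3e4  # many rings
  # centred sphere
  ctr <- estimate_sphere_center(sphere_phase(p, C, 128, 128))
  expect_lte(max(abs(ctr - c(128, 128))), 2)
  # offset sphere (u0 + 37, v0 - 21)
  ctr2 <- estimate_sphere_center(sphere_phase(p, C, 165, 107))
  expect_lte(abs(ctr2[["h"]] - 165), 2)
  expect_lte(abs(ctr2[["g"]] - 107), 2)
})

test_that("centre estimation fails cleanly without rings", {
  expect_error(estimate_sphere_center(phase_map(matrix(0.3, 64, 64))),
               "centre not found")
})

test_that("blank subtraction equals the single-shot method up to a constant", {
  p <- std_params(256)
  C <- 6.5e4
  sample_tr <- truth_from_bins(p, offset_bins = c(60, 70), C = C,
                               pattern = list(kind = "disc"))
  blank_tr <- truth_from_bins(p, offset_bins = c(60, 70), C = C)
  roi <- spectrum_roi(68, 58, 100, 100)
  tilt <- tilt_from_roi(roi, p)
  rec_phase <- function(tr) {
    S <- compute_spectrum(simulate_hologram(tr))
    ft <- compensate_tilt(filter_plus_one(S, roi), tilt)
    phase_map(Arg(ft$values))
  }
  sub <- subtract_blank(rec_phase(sample_tr), rec_phase(blank_tr))
  # single-shot route with true parameters
  S <- compute_spectrum(simulate_hologram(sample_tr))
  ft <- compensate_tilt(filter_plus_one(S, roi), tilt)
  prop <- compensate_sphere(ft, spherical_wavefront(C, C, h = 128, g = 128))
  d <- wrap_phase(sub$values - prop$values)
  expect_lt(circular_sd(d), 0.05)
  # identical inputs cancel exactly
  z <- subtract_blank(prop, prop)
  expect_equal(max(abs(z$values)), 0)
  # +5% curvature-mismatched blank leaves residual rings
  blank_bad <- truth_from_bins(p, offset_bins = c(60, 70), C = 1.05 * C)
  sub_bad <- subtract_blank(rec_phase(sample_tr), rec_phase(blank_bad))
  bg <- sample_tr$object_phase == 0
  expect_gt(circular_sd(sub_bad$values[bg]), circular_sd(sub$values[bg]))
})

test_that("unwrapping restores a 6-pi ramp exactly", {
  n <- 128
  ramp <- matrix(seq(0, 6 * pi, length.out = n), n, n, byrow = TRUE)
  u <- unwrap_phase(phase_map(wrap_phase(ramp)))
  expect_false(u$wrapped)
  resid <- (u$values - u$values[1, 1]) - (ramp - ramp[1, 1])
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("unwrapping is congruent to its input modulo 2*pi", {
  p <- std_params(128)
  w <- sphere_phase(p, 2e4, 80, 50)
  u <- unwrap_phase(w)
  k <- (u$values - w$values) / (2 * pi)
  expect_lt(max(abs(k - round(k))), 1e-9)
})

test_that("unwrapping recovers a five-wrap paraboloid", {
  p <- std_params(128)
  m <- matrix(0:127, 128, 128, byrow = TRUE)
  n <- matrix(0:127, 128, 128)
  true_ph <- 10 * pi * ((m - 63.5)^2 + (n - 63.5)^2) / (2 * 63.5^2)
  u <- unwrap_phase(phase_map(wrap_phase(true_ph)))
  resid <- u$values - true_ph
  resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)), 0.01)
})
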