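test_that("patterns honour their geometry and height contracts", {
  # QPT-nominal disc height: 2*pi*(1.52-1)*0.350/0.532
  d <- make_pattern("disc", 128)
  expect_equal(max(d$values), 2 * pi * 0.52 * 0.350 / 0.532, tolerance = 1e-12)
  expect_equal(signif(max(d$values), 5), 2.1496, tolerance = 1e-4)
  expect_equal(min(d$values), 0)
  # null object
  expect_equal(max(abs(make_pattern("star", 64, height = 0)$values)), 0)
  # wedding cake: steps at 0, h, 2h, 3h
  wc <- make_pattern("wedding_cake", 128, height = 1.1, steps = 3)
  expect_equal(sort(unique(c(wc$values))), c(0, 1.1, 2.2, 3.3),
               tolerance = 1e-12)
  expect_error(make_pattern("pyramid", 128), "arg")
  expect_error(make_pattern("disc", 32), "size")
})

test_that("the null interference case gives a constant hologram of 4", {
  p <- std_params(64)
  tr <- simulation_truth(p, tilt_angles(0, 0))
  h <- simulate_hologram(tr)
  expect_equal(h$values, matrix(4, 64, 64), tolerance = 1e-12)
})

test_that("a simulated carrier lands on the predicted spectral bins", {
  p <- std_params(256)
  # sin(theta) chosen for a 50-bin offset: fringe period 5.12 px
  tr <- truth_from_bins(p, offset_bins = c(50, 0))
  S <- Mod(compute_spectrum(simulate_hologram(tr))$values)
  S[129, 129] <- 0
  pk <- which(S > 0.99 * max(S), arr.ind = TRUE)  # +/-1 peaks tie up to fp
  expect_setequal(pk[, "col"], c(129 - 50, 129 + 50))
  expect_setequal(unique(pk[, "row"]), 129)
})

test_that("support width scales inversely with curvature", {
  p <- acq_params(1024, 1024, 5.86, 0.532)
  C <- 2.644e5
  tr <- truth_from_bins(p, offset_bins = c(0, 170), C = C)
  h <- suppressWarnings(simulate_hologram(tr))
  w <- measure_support_width(compute_spectrum(h))
  expect_lte(abs(w[["M"]] - 256), 2)
})

test_that("Nyquist-violating carriers raise an aliasing error", {
  p <- std_params(64)
  # |sin theta| beyond lambda/(2*delta)
  bad <- tilt_angles(asin(0.9 * 0.532 / 5.86), 0)
  expect_error(simulate_hologram(simulation_truth(p, bad)), "aliasing|Nyquist")
})

test_that("noise is reproducible from the manifest seed", {
  p <- std_params(64)
  tr <- truth_from_bins(p, offset_bins = c(10, 8), noise_sd = 0.05,
                        rng_seed = 77L)
  h1 <- simulate_hologram(tr)
  h2 <- simulate_hologram(tr)
  expect_identical(h1$values, h2$values)
  tr2 <- truth_from_bins(p, offset_bins = c(10, 8), noise_sd = 0.05,
                         rng_seed = 78L)
  expect_false(identical(simulate_hologram(tr2)$values, h1$values))
})

test_that("truth manifests round-trip losslessly", {
  p <- std_params(128)
  tr <- truth_from_bins(p, offset_bins = c(30, 25), C = 4e4,
                        center = c(70, 58), sign = -1,
                        pattern = list(kind = "wedding_cake", height = 0.9),
                        noise_sd = 0.02, rng_seed = 123L)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_manifest(tr, path)
  back <- read_truth_manifest(path)
  expect_equal(back$params, tr$params)
  expect_equal(back$tilt$theta_x, tr$tilt$theta_x, tolerance = 1e-12)
  expect_equal(back$sphere, tr$sphere)
  expect_equal(back$object_phase, tr$object_phase)
  # JSON serializes doubles at 15 significant digits; the regenerated
  # hologram agrees to that precision and the seeded noise is identical
  expect_equal(simulate_hologram(back)$values, simulate_hologram(tr)$values,
               tolerance = 1e-12)
})

test_that("telecentric truth is flagged, not numeric, in the manifest", {
  p <- std_params(64)
  tr <- truth_from_bins(p, offset_bins = c(10, 8), C = NULL)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_manifest(tr, path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true(rec$sphere$telecentric)
  expect_null(rec$sphere$C_x)
})

test_that("curvature from f_TL and z follows C = f^2/(f - z)", {
  p <- std_params(64)
  tr <- simulation_truth(p, tilt_angles(0.01, 0), f_TL = 2e5, z = 1.5e5)
  expect_equal(tr$sphere$C_x, (2e5)^2 / (2e5 - 1.5e5), tolerance = 1e-12)
  expect_equal(tr$sphere$sign, 1)
  # z = f_TL is the telecentric limit
  tr2 <- simulation_truth(p, tilt_angles(0.01, 0), f_TL = 2e5, z = 2e5)
  expect_true(tr2$sphere$telecentric)
})

test_that("end-to-end recovery holds across pattern kinds", {
  p <- std_params(256)
  C <- 1.3e5  # support ~33 px at 256 leaves a usable object passband
  roi <- spectrum_roi(128 - 64, 128 - 64, 126, 126)
  for (kind in c("disc", "wedding_cake", "blobs", "star", "bars")) {
    tr <- truth_from_bins(p, offset_bins = c(64, 64), C = C,
                          pattern = list(kind = kind, height = 1.2))
    h <- simulate_hologram(tr)
    rec <- reconstruct(h, roi = roi,
                       sphere = spherical_wavefront(C, C, h = 128, g = 128),
                       unwrap = TRUE)
    u <- rec$unwrapped$values
    u <- u - mean(u - tr$object_phase)
    s <- ssim_metric(u, tr$object_phase)
    # binary sharp-edged targets are limited by the filtered passband
    # (Gibbs/blur), not by the compensation; their floor is lower here
    lim <- if (kind %in% c("disc", "star", "bars")) 0.85 else 0.95
    expect_gte(s, lim)
  }
})
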