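# Shared fixtures built in code. Default geometry mirrors the reference
# acquisition: 5.86 um pixels, 532 nm laser; grids are scaled down so the
# suite stays fast.

std_params <- function(X = 256L, Y = X) acq_params(X, Y, 5.86, 0.532)

# one spectral bin expressed in sin(theta) units
bin_sine <- function(params) params$wavelength / (params$X * params$delta_xy)

# pure spherical wrapped phase map (no hologram), 0-based centre (h, g)
sphere_phase <- function(params, C, h, g, sign = 1) {
  m <- matrix(0:(params$X - 1), params$Y, params$X, byrow = TRUE)
  n <- matrix(0:(params$Y - 1), params$Y, params$X)
  ph <- sign * pi / params$wavelength * params$delta_xy^2 *
    ((m - h)^2 / C + (n - g)^2 / C)
  phase_map(wrap_phase(ph))
}

# telecentric hologram whose sideband is a compact smooth blob spectrum:
# ideal carrier-recovery target
blob_hologram <- function(params, offset_bins, rng_seed = 1L) {
  tr <- truth_from_bins(params, offset_bins = offset_bins, C = NULL,
                        pattern = list(kind = "blobs", height = 1.2),
                        rng_seed = rng_seed)
  list(truth = tr, holo = simulate_hologram(tr))
}

# centred 2D spectrum of an arbitrary (complex) matrix, independent of the
# package's internal shift helpers
centred_spectrum_of <- function(v) {
  s <- stats::fft(v)
  nr <- nrow(s); nc <- ncol(s)
  ri <- ((seq_len(nr) - 1L + nr - nr %/% 2L) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L + nc - nc %/% 2L) %% nc) + 1L
  s[ri, ci, drop = FALSE]
}

expect_wrapped <- function(pm) {
  expect_true(all(pm$values > -pi - 1e-12 & pm$values <= pi + 1e-12))
}
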