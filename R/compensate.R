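# Removal of the off-axis tilt and the non-telecentric spherical wavefront
# from the filtered image-plane field.

#' Digital reference wave
#'
#' The discrete plane wave that cancels the off-axis carrier retained in the
#' filtered field:
#' `r_D(m, n) = exp(i * 2*pi/lambda * ((m - u0) sin(theta_x) + (n - v0) sin(theta_y)) * delta_xy)`
#' on centred pixel coordinates. Unit modulus everywhere.
#'
#' @param tilt a [tilt_angles()].
#' @param params an [acq_params()].
#' @return A [complex_field()].
#' @export
digital_reference_wave <- function(tilt, params) {
  stopifnot(inherits(tilt, "tilt_angles"), inherits(params, "acq_params"))
  dc <- dc_bins(params)
  g <- pixel_grids(params)
  arg <- 2 * pi / params$wavelength * params$delta_xy *
    ((g$m - dc[["u0"]]) * sin(tilt$theta_x) +
     (g$n - dc[["v0"]]) * sin(tilt$theta_y))
  complex_field(exp(1i * arg), params)
}

#' Compensate the off-axis tilt
#'
#' Pointwise product of the field with the digital reference wave, with the
#' sign convention that a carrier whose +1 order sits at spectral offset
#' `(u0 - P, v0 - Q)` is cancelled by the tilt returned from
#' [tilt_from_roi()] on that ROI.
#'
#' @param field a [complex_field()] (typically `h_F` from
#'   [filter_plus_one()]).
#' @param tilt a [tilt_angles()].
#' @return A [complex_field()] with the carrier removed.
#' @export
compensate_tilt <- function(field, tilt) {
  stopifnot(inherits(field, "complex_field"), inherits(tilt, "tilt_angles"))
  rd <- digital_reference_wave(tilt, field$params)
  complex_field(field$values * rd$values, field$params)
}

#' Estimate the centre of the spherical wavefront
#'
#' After tilt compensation, the wrapped phase of a non-telecentric field shows
#' concentric rings around the sphere centre. The phase is normalized to
#' `[0, 1]`, binarized at Otsu's global threshold, connected components are
#' labelled, and among regions whose area is at least `min_area_frac` of the
#' image the one with the lowest eccentricity is selected (the most circular
#' ring or innermost disc); ties go to the largest area. The returned centre
#' is the centre of that region's bounding box, in 0-based pixels.
#'
#' @param phase a wrapped [phase_map()].
#' @param min_area_frac minimum region area as a fraction of total pixels
#'   (default 0.001); rejects speckle-sized components.
#' @return Named numeric vector `c(h = column, g = row)`, 0-based.
#' @export
estimate_sphere_center <- function(phase, min_area_frac = 0.001) {
  stopifnot(inherits(phase, "phase_map"))
  if (!phase$wrapped) stop("centre estimation expects a wrapped phase map",
                           call. = FALSE)
  v <- phase$values
  rng <- range(v)
  if (rng[2] - rng[1] < 1e-9)
    stop("centre not found: constant phase map has no rings to segment",
         call. = FALSE)
  norm <- (v - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  lab <- EBImage::bwlabel(EBImage::Image(norm > th))
  labm <- EBImage::imageData(lab)
  nlab <- max(labm)
  if (nlab < 1)
    stop("centre not found: no region above threshold", call. = FALSE)
  fm <- EBImage::computeFeatures.moment(lab)
  fs <- EBImage::computeFeatures.shape(lab)
  area <- fs[, "s.area"]
  ecc <- fm[, "m.eccentricity"]
  floor_px <- min_area_frac * length(v)
  ok <- which(area >= floor_px)
  if (length(ok) == 0)
    stop("centre not found: no region above the minimum-area floor",
         call. = FALSE)
  best <- ok[order(ecc[ok], -area[ok])][1]
  px <- which(labm == best, arr.ind = TRUE)
  c(h = (min(px[, 2]) + max(px[, 2])) / 2 - 1,
    g = (min(px[, 1]) + max(px[, 1])) / 2 - 1)
}

#' Conjugated digital spherical wavefront
#'
#' The unit-modulus field that cancels the spherical factor of curvature
#' `(C_x, C_y)` centred at pixel `(h, g)`:
#' `uS*(m, n) = exp(-i * pi/lambda * ((m-h)^2/C_x + (n-g)^2/C_y) * delta_xy^2)`,
#' with the overall sign flipped for a diverging wavefront
#' (`sphere$sign == -1`). The telecentric flag yields the constant unit field.
#'
#' @param sphere a [spherical_wavefront()] with centre set (unless
#'   telecentric).
#' @param params an [acq_params()].
#' @return A [complex_field()].
#' @export
conjugate_spherical_wave <- function(sphere, params) {
  stopifnot(inherits(sphere, "spherical_wavefront"),
            inherits(params, "acq_params"))
  if (sphere$telecentric) {
    return(complex_field(matrix(1 + 0i, params$Y, params$X), params))
  }
  if (!is.finite(sphere$h) || !is.finite(sphere$g))
    stop("spherical wavefront centre (h, g) is unset", call. = FALSE)
  g <- pixel_grids(params)
  arg <- -sphere$sign * pi / params$wavelength * params$delta_xy^2 *
    ((g$m - sphere$h)^2 / sphere$C_x + (g$n - sphere$g)^2 / sphere$C_y)
  complex_field(exp(1i * arg), params)
}

#' Compensate the spherical wavefront and extract the phase
#'
#' Multiplies the tilt-compensated field by the conjugated spherical
#' wavefront and returns the wrapped phase `angle(field * uS*)`. Since the
#' compensation wave has unit modulus, the amplitude is untouched.
#'
#' @param field a [complex_field()].
#' @param sphere a [spherical_wavefront()].
#' @return A wrapped [phase_map()].
#' @export
compensate_sphere <- function(field, sphere) {
  stopifnot(inherits(field, "complex_field"))
  us <- conjugate_spherical_wave(sphere, field$params)
  phase_map(Arg(field$values * us$values), wrapped = TRUE)
}

#' Dual-shot subtraction baseline
#'
#' Classic two-hologram compensation: subtract the reconstructed phase of a
#' blank (sample-free) hologram from the sample's phase, wrapping the
#' difference back into `(-pi, pi]`. Kept as a baseline against which the
#' single-shot spectral method is compared.
#'
#' @param sample_phase,blank_phase wrapped [phase_map()]s of equal shape.
#' @return A wrapped [phase_map()].
#' @export
subtract_blank <- function(sample_phase, blank_phase) {
  stopifnot(inherits(sample_phase, "phase_map"),
            inherits(blank_phase, "phase_map"))
  a <- sample_phase$values; b <- blank_phase$values
  if (!all(dim(a) == dim(b)))
    stop("sample and blank phase maps have different shapes", call. = FALSE)
  phase_map(wrap_phase(a - b), wrapped = TRUE)
}
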