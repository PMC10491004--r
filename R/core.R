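# Closed-form relations between spectral measurements and physical
# parameters of the off-axis non-telecentric system.

#' Interference tilt from the +1-order centroid
#'
#' The carrier imprinted by the off-axis geometry shifts the object spectrum
#' away from DC; the offset of the +1-order centroid gives the tilt per axis:
#' `theta_x = asin((u0 - P) * lambda / (X * delta_xy))` and likewise for y.
#'
#' @param roi a [spectrum_roi()] whose centre is the +1-order centroid.
#' @param params an [acq_params()].
#' @return A [tilt_angles()] object.
#' @examples
#' p <- acq_params(1024, 1024, 5.86, 0.532)
#' roi <- spectrum_roi(P = 512 - 200, Q = 512, M = 64, N = 64)
#' tilt_from_roi(roi, p)
#' @export
tilt_from_roi <- function(roi, params) {
  validate_roi(roi, params)
  dc <- dc_bins(params)
  sx <- (dc[["u0"]] - roi$P) * params$wavelength / (params$X * params$delta_xy)
  sy <- (dc[["v0"]] - roi$Q) * params$wavelength / (params$Y * params$delta_xy)
  if (abs(sx) > 1)
    stop(sprintf("invalid carrier along x: |sin theta_x| = %.4g > 1", abs(sx)),
         call. = FALSE)
  if (abs(sy) > 1)
    stop(sprintf("invalid carrier along y: |sin theta_y| = %.4g > 1", abs(sy)),
         call. = FALSE)
  tilt_angles(asin(sx), asin(sy))
}

#' Spherical curvature from the +1-order extent
#'
#' In a non-telecentric system the +1 order's compact support is a rectangle
#' whose size grows linearly with the inverse curvature of the distorting
#' spherical wavefront: `M = (X * delta_xy)^2 / (lambda * C)`. Inverting,
#' `C_x = (X * delta_xy)^2 / (lambda * M)` and
#' `C_y = (Y * delta_xy)^2 / (lambda * N)`.
#'
#' Only the curvature magnitudes can be read off the spectrum; the
#' converging/diverging sign is resolved later (see [reconstruct()]).
#'
#' @param roi a [spectrum_roi()] sized to the +1-order support.
#' @param params an [acq_params()].
#' @return A [spherical_wavefront()] with curvatures set and centre unset.
#' @examples
#' p <- acq_params(1024, 1024, 5.86, 0.532)
#' curvature_from_roi(spectrum_roi(312, 512, 256, 256), p)
#' @export
curvature_from_roi <- function(roi, params) {
  stopifnot(inherits(roi, "spectrum_roi"), inherits(params, "acq_params"))
  if (roi$M < 1 || roi$N < 1)
    stop("degenerate ROI: M and N must be >= 1", call. = FALSE)
  cx <- (params$X * params$delta_xy)^2 / (params$wavelength * roi$M)
  cy <- (params$Y * params$delta_xy)^2 / (params$wavelength * roi$N)
  spherical_wavefront(C_x = cx, C_y = cy)
}

#' Percent error of an estimate against a reference
#'
#' `PE = |estimate - reference| / |reference| * 100`.
#'
#' @param estimate,reference scalars; `reference` must be nonzero.
#' @return Percent error (non-negative scalar, percent).
#' @examples
#' percent_error(0.5769, 0.5707) # ~1.09 %
#' @export
percent_error <- function(estimate, reference) {
  if (!is.finite(reference) || reference == 0)
    stop("percent error undefined for zero reference", call. = FALSE)
  abs(estimate - reference) / abs(reference) * 100
}

#' Coherent diffraction limit
#'
#' Lateral resolution of a coherent imaging system, `d = lambda / NA`.
#'
#' @param wavelength illumination wavelength (micrometres).
#' @param na numerical aperture of the objective.
#' @return Resolution in the unit of `wavelength`.
#' @examples
#' coherent_resolution(0.532, 0.75) # ~0.71 um
#' @export
coherent_resolution <- function(wavelength, na) {
  stopifnot(wavelength > 0, na > 0)
  wavelength / na
}
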