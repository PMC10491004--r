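#' Acquisition parameters of the hologram sensor
#'
#' Bundles the sensor geometry and illumination wavelength needed by every
#' spectral relation in the package: pixel counts `X` (columns) and `Y` (rows),
#' the pixel pitch and the laser wavelength. The pitch and wavelength must be
#' expressed in the same length unit; micrometres are used throughout the
#' package and its documentation.
#'
#' The spectrum is handled in the centred convention: after the FFT shift the
#' DC bin sits at the 0-based coordinates `(u0, v0) = (floor(X/2), floor(Y/2))`.
#' For even sensors this coincides with the common 1-based `(X/2 + 1, Y/2 + 1)`
#' convention. Odd-sized sensors are supported but unusual for cameras, so they
#' trigger a warning.
#'
#' @param X integer, number of pixels along x (columns), at least 8.
#' @param Y integer, number of pixels along y (rows), at least 8.
#' @param delta_xy pixel pitch in micrometres (square pixels), positive.
#' @param wavelength illumination wavelength in micrometres, positive.
#' @return An object of class `acq_params`.
#' @examples
#' p <- acq_params(1024, 1024, delta_xy = 5.86, wavelength = 0.532)
#' dc_bins(p)
#' @export
acq_params <- function(X, Y, delta_xy, wavelength) {
  X <- as.integer(X); Y <- as.integer(Y)
  if (is.na(X) || is.na(Y) || X < 8L || Y < 8L)
    stop("X and Y must be integers >= 8", call. = FALSE)
  if (!is.finite(delta_xy) || delta_xy <= 0)
    stop("delta_xy must be a positive length (micrometres)", call. = FALSE)
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("wavelength must be a positive length (micrometres)", call. = FALSE)
  if (X %% 2L == 1L || Y %% 2L == 1L)
    warning("odd-sized sensor: DC bin placed at (floor(X/2), floor(Y/2))",
            call. = FALSE)
  structure(list(X = X, Y = Y, delta_xy = delta_xy, wavelength = wavelength),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("<acq_params> %d x %d px, pitch %g um, wavelength %g um\n",
              x$X, x$Y, x$delta_xy, x$wavelength))
  invisible(x)
}

#' DC bin coordinates of the centred spectrum
#'
#' @param params an [acq_params()] object.
#' @return Integer vector `c(u0, v0)`: 0-based column and row of the DC bin.
#' @export
dc_bins <- function(params) {
  stopifnot(inherits(params, "acq_params"))
  c(u0 = params$X %/% 2L, v0 = params$Y %/% 2L)
}

#' Rectangular region of interest around the +1 diffraction order
#'
#' Describes where the +1 term sits in the centred hologram spectrum:
#' centre `(P, Q)` (0-based column/row in spectral pixels) and extents
#' `M` x `N` (width x height). The rectangle covers spectral bins with
#' `|u - P| <= M/2` and `|v - Q| <= N/2`.
#'
#' @param P,Q 0-based centre column and row of the +1 order.
#' @param M,N width and height of the rectangle in spectral pixels (>= 1).
#' @return An object of class `spectrum_roi`.
#' @seealso [validate_roi()], [tilt_from_roi()], [curvature_from_roi()]
#' @export
spectrum_roi <- function(P, Q, M, N) {
  if (!is.finite(M) || !is.finite(N) || M < 1 || N < 1)
    stop("degenerate ROI: M and N must be >= 1 spectral pixel", call. = FALSE)
  structure(list(P = as.numeric(P), Q = as.numeric(Q),
                 M = as.numeric(M), N = as.numeric(N)),
            class = "spectrum_roi")
}

#' @export
print.spectrum_roi <- function(x, ...) {
  cat(sprintf("<spectrum_roi> centre (P=%g, Q=%g), size %g x %g px\n",
              x$P, x$Q, x$M, x$N))
  invisible(x)
}

#' Validate a spectrum ROI against the sensor geometry
#'
#' Checks that the rectangle lies within the spectrum bounds and does not
#' contain the DC bin (DC leakage into the filtered field would swamp the
#' object term).
#'
#' @param roi a [spectrum_roi()].
#' @param params an [acq_params()].
#' @return `roi`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_roi <- function(roi, params) {
  stopifnot(inherits(roi, "spectrum_roi"), inherits(params, "acq_params"))
  dc <- dc_bins(params)
  if (roi$P - roi$M / 2 < 0 || roi$P + roi$M / 2 > params$X - 1 ||
      roi$Q - roi$N / 2 < 0 || roi$Q + roi$N / 2 > params$Y - 1)
    stop("ROI rectangle exceeds the spectrum bounds", call. = FALSE)
  if (abs(dc["u0"] - roi$P) <= roi$M / 2 && abs(dc["v0"] - roi$Q) <= roi$N / 2)
    stop("ROI contains the DC bin; shrink or move it away from (u0, v0)",
         call. = FALSE)
  invisible(roi)
}

#' Off-axis interference tilt angles
#'
#' The angle between the object and reference wavevectors, per axis, in
#' radians. The carrier they imprint must stay below the Nyquist limit of the
#' sensor: `|sin(theta)| <= wavelength / (2 * delta_xy)`.
#'
#' @param theta_x,theta_y tilt angles in radians.
#' @param params optional [acq_params()]; when supplied the Nyquist bound is
#'   checked.
#' @return An object of class `tilt_angles`.
#' @export
tilt_angles <- function(theta_x, theta_y, params = NULL) {
  if (!is.finite(theta_x) || !is.finite(theta_y))
    stop("tilt angles must be finite", call. = FALSE)
  if (!is.null(params)) {
    lim <- params$wavelength / (2 * params$delta_xy)
    for (ax in c("x", "y")) {
      s <- abs(sin(if (ax == "x") theta_x else theta_y))
      if (s > lim)
        stop(sprintf("carrier exceeds Nyquist along %s: |sin theta| = %.4g > %.4g",
                     ax, s, lim), call. = FALSE)
    }
  }
  structure(list(theta_x = theta_x, theta_y = theta_y), class = "tilt_angles")
}

#' @export
print.tilt_angles <- function(x, ...) {
  cat(sprintf("<tilt_angles> theta_x = %.6g rad, theta_y = %.6g rad\n",
              x$theta_x, x$theta_y))
  invisible(x)
}

#' Spherical wavefront of a non-telecentric imaging system
#'
#' Parameters of the parabolic (paraxial spherical) phase factor that a
#' non-telecentric microscope imprints on the image-plane field: curvatures
#' `C_x`, `C_y` (micrometres; equal for square sensors), centre `(h, g)` in
#' 0-based pixel coordinates (column, row), and a sign distinguishing
#' converging (`+1`) from diverging (`-1`) wavefronts. The telecentric limit
#' (curvature to infinity, unit spherical factor) is represented by the
#' `telecentric` flag rather than a numeric sentinel.
#'
#' @param C_x,C_y curvatures along x and y in micrometres; finite and nonzero
#'   unless `telecentric = TRUE`.
#' @param h,g centre of the wavefront in 0-based pixels (column `h`, row `g`);
#'   `NA` when not yet estimated.
#' @param sign `+1` (converging) or `-1` (diverging).
#' @param telecentric logical; `TRUE` means the unit spherical factor.
#' @return An object of class `spherical_wavefront`.
#' @export
spherical_wavefront <- function(C_x = NA_real_, C_y = NA_real_,
                                h = NA_real_, g = NA_real_,
                                sign = 1, telecentric = FALSE) {
  if (!telecentric) {
    if (!is.finite(C_x) || !is.finite(C_y) || C_x == 0 || C_y == 0)
      stop("curvatures must be finite and nonzero (or set telecentric = TRUE)",
           call. = FALSE)
  }
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1", call. = FALSE)
  structure(list(C_x = C_x, C_y = C_y, h = as.numeric(h), g = as.numeric(g),
                 sign = sign, telecentric = isTRUE(telecentric)),
            class = "spherical_wavefront")
}

#' @export
print.spherical_wavefront <- function(x, ...) {
  if (x$telecentric) {
    cat("<spherical_wavefront> telecentric (unit factor)\n")
  } else {
    cat(sprintf(
      "<spherical_wavefront> C = (%.6g, %.6g) um, centre (h=%g, g=%g), %s\n",
      x$C_x, x$C_y, x$h, x$g,
      if (x$sign > 0) "converging" else "diverging"))
  }
  invisible(x)
}
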