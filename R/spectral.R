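# Fourier-domain analysis of the hologram: centred spectrum, +1-order ROI
# suggestion, spatial filtering back to the image plane, and support-width
# measurement.

fftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- ((seq_len(nr) - 1L + nr - nr %/% 2L) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L + nc - nc %/% 2L) %% nc) + 1L
  x[ri, ci, drop = FALSE]
}

ifftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- ((seq_len(nr) - 1L + nr %/% 2L) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L + nc %/% 2L) %% nc) + 1L
  x[ri, ci, drop = FALSE]
}

#' Centred spectrum of a hologram
#'
#' Computes the unnormalized 2D discrete Fourier transform of the hologram
#' and relocates the zero-frequency component to the centre bin
#' `(u0, v0) = (floor(X/2), floor(Y/2))` (0-based). With this convention
#' Parseval's identity reads `sum(|S|^2) / (X*Y) == sum(h^2)`.
#'
#' @param holo a [hologram()].
#' @return A [complex_field()] holding the centred spectrum.
#' @export
compute_spectrum <- function(holo) {
  stopifnot(inherits(holo, "hologram"))
  complex_field(fftshift2(stats::fft(holo$values)), holo$params)
}

#' Suggest a +1-order region of interest automatically
#'
#' Convenience seed for the ROI that the reconstruction pipeline needs:
#' masks a disc around DC, compresses the magnitude with `log1p`, thresholds
#' at Otsu's level, keeps connected components in the half-plane above DC
#' (rows `< v0`), and returns the bounding box of the largest one. The result
#' is deterministic; users wanting the slight overestimate that preserves
#' high-frequency object detail should pad `M`/`N` themselves.
#'
#' @param spectrum a centred spectrum ([complex_field()], see
#'   [compute_spectrum()]).
#' @param dc_exclusion_radius radius in spectral pixels of the disc masked
#'   around DC; default `max(X, Y) / 20`.
#' @return A [spectrum_roi()].
#' @export
suggest_roi <- function(spectrum, dc_exclusion_radius = NULL) {
  stopifnot(inherits(spectrum, "complex_field"))
  p <- spectrum$params
  dc <- dc_bins(p)
  r <- dc_exclusion_radius %||% (max(p$X, p$Y) / 20)
  g <- pixel_grids(p)
  mag <- log1p(Mod(spectrum$values))
  mag[(g$m - dc[["u0"]])^2 + (g$n - dc[["v0"]])^2 <= r^2] <- 0
  rng <- range(mag)
  if (rng[2] - rng[1] < 1e-12)
    stop("ROI suggestion failed: no sideband energy; supply the ROI manually",
         call. = FALSE)
  norm <- (mag - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  lab <- EBImage::bwlabel(EBImage::Image(norm > th))
  labm <- EBImage::imageData(lab)
  nlab <- max(labm)
  if (nlab < 1)
    stop("ROI suggestion failed: no component above threshold; supply the ROI manually",
         call. = FALSE)
  # candidate components: centroid row above DC (smaller row index)
  best <- NULL; best_area <- -Inf; best_row <- Inf
  for (k in seq_len(nlab)) {
    px <- which(labm == k, arr.ind = TRUE)
    cr <- mean(px[, 1]) - 1   # 0-based centroid row
    if (cr >= dc[["v0"]]) next
    area <- nrow(px)
    if (area > best_area || (area == best_area && cr < best_row)) {
      best <- px; best_area <- area; best_row <- cr
    }
  }
  if (is.null(best))
    stop("ROI suggestion failed: no sideband above DC; supply the ROI manually",
         call. = FALSE)
  r0 <- min(best[, 1]) - 1L; r1 <- max(best[, 1]) - 1L
  c0 <- min(best[, 2]) - 1L; c1 <- max(best[, 2]) - 1L
  roi <- spectrum_roi(P = (c0 + c1) / 2, Q = (r0 + r1) / 2,
                      M = max(1, c1 - c0), N = max(1, r1 - r0))
  validate_roi(roi, p)
  roi
}

#' Filter the +1 diffraction order
#'
#' Zeroes every spectral bin outside the ROI rectangle and inverse-transforms
#' back to the image plane, yielding the filtered complex field `h_F` (the
#' object field times the residual tilt and spherical factors). The operation
#' is a linear projection: applying it twice equals applying it once.
#'
#' @param spectrum a centred spectrum ([complex_field()]).
#' @param roi a [spectrum_roi()]; must not contain the DC bin.
#' @param apodize fraction of the ROI half-width over which a raised-cosine
#'   edge tapers the mask (default 0: hard rectangular crop, matching the
#'   classic rectangle filter; a value like 0.2 suppresses the ringing the
#'   hard edge produces on sharp objects).
#' @return A [complex_field()] holding `h_F` (same shape as the input).
#' @export
filter_plus_one <- function(spectrum, roi, apodize = 0) {
  stopifnot(inherits(spectrum, "complex_field"))
  p <- spectrum$params
  validate_roi(roi, p)
  g <- pixel_grids(p)
  if (apodize <= 0) {
    mask <- (abs(g$m - roi$P) <= roi$M / 2) *
            (abs(g$n - roi$Q) <= roi$N / 2)
  } else {
    edge1d <- function(d, half) {
      t <- pmax(0, pmin(1, (half - d) / (apodize * half)))
      0.5 - 0.5 * cos(pi * t)
    }
    mask <- edge1d(abs(g$m - roi$P), roi$M / 2) *
            edge1d(abs(g$n - roi$Q), roi$N / 2)
  }
  s <- spectrum$values * mask
  field <- stats::fft(ifftshift2(s), inverse = TRUE) / (p$X * p$Y)
  complex_field(field, p)
}

#' Measure the +1-order support width in the spectrum
#'
#' Diagnostic used to validate the linear relation between support size and
#' inverse curvature. A disc around DC is masked, the magnitude is collapsed
#' by a columnwise (and rowwise) maximum, and the support edge is located at
#' half the plateau level, where the plateau level is the median magnitude
#' among bins above a quarter of the peak. This edge rule is robust both to
#' the ringing overshoot at the support edges and to the slowly decaying
#' tails outside it.
#'
#' @param spectrum a centred spectrum ([complex_field()]).
#' @param dc_exclusion_radius disc radius masked around DC (default
#'   `max(X, Y)/40`).
#' @return Named numeric vector `c(M = columns, N = rows)` of the measured
#'   support extent.
#' @export
measure_support_width <- function(spectrum, dc_exclusion_radius = NULL) {
  stopifnot(inherits(spectrum, "complex_field"))
  p <- spectrum$params
  dc <- dc_bins(p)
  r <- dc_exclusion_radius %||% (max(p$X, p$Y) / 40)
  g <- pixel_grids(p)
  mag <- Mod(spectrum$values)
  mag[(g$m - dc[["u0"]])^2 + (g$n - dc[["v0"]])^2 <= r^2] <- 0
  width1d <- function(prof) {
    pk <- max(prof)
    if (pk <= 0) return(0)
    plateau <- stats::median(prof[prof > 0.25 * pk])
    idx <- which(prof > 0.5 * plateau)
    max(idx) - min(idx) + 1
  }
  c(M = width1d(apply(mag, 2, max)), N = width1d(apply(mag, 1, max)))
}
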