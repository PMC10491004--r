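# Forward model of off-axis non-telecentric hologram formation, phase-target
# generators and ground-truth manifests. This is the test bed for every
# estimator in the package.

#' Synthetic phase-target patterns
#'
#' Binary or stepped phase objects emulating common calibration targets:
#' `star` (radial spoke target), `bars` (three-bar resolution groups),
#' `wedding_cake` (concentric stacked discs with equal phase steps), `blobs`
#' (smooth Gaussian bumps) and `disc` (a single flat disc). The background is
#' exactly 0.
#'
#' @param kind pattern name.
#' @param size image side in pixels (square, >= 64).
#' @param height phase height in radians of one step (total height for
#'   `blobs`); the default 2.1497 rad corresponds to a 350 nm feature of
#'   refractive index 1.52 in air at 532 nm
#'   (`2*pi*(1.52 - 1)*0.350/0.532`).
#' @param steps number of steps for `wedding_cake` (default 3).
#' @return An unwrapped [phase_map()] (`wrapped = FALSE`); values in
#'   `[0, steps * height]`.
#' @export
make_pattern <- function(kind = c("star", "bars", "wedding_cake", "blobs",
                                  "disc"),
                         size = 256L, height = 2 * pi * 0.52 * 0.350 / 0.532,
                         steps = 3L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 64L) stop("pattern size must be >= 64 pixels", call. = FALSE)
  c0 <- (size - 1) / 2
  m <- matrix(0:(size - 1), size, size, byrow = TRUE) - c0
  n <- matrix(0:(size - 1), size, size) - c0
  r <- sqrt(m^2 + n^2)
  v <- switch(kind,
    disc = ifelse(r <= 0.3 * size, height, 0),
    star = {
      ang <- atan2(n, m)
      sector <- floor((ang + pi) / (2 * pi) * 16) %% 2
      ifelse(sector == 0 & r <= 0.4 * size & r > 0.02 * size, height, 0)
    },
    bars = {
      out <- matrix(0, size, size)
      # three vertical and three horizontal bars per group, two scales
      for (sc in c(1, 0.5)) {
        w <- round(0.04 * size * sc); gap <- w
        len <- round(0.18 * size * sc)
        ox <- round(size * ifelse(sc == 1, 0.25, 0.62))
        oy <- round(size * 0.3)
        for (k in 0:2) {
          cols <- (ox + k * (w + gap)):(ox + k * (w + gap) + w - 1)
          out[oy:(oy + len - 1), cols] <- height
          rows <- (oy + len + gap + k * (w + gap)):
                  (oy + len + gap + k * (w + gap) + w - 1)
          out[rows, ox:(ox + len - 1)] <- height
        }
      }
      out
    },
    wedding_cake = {
      out <- matrix(0, size, size)
      radii <- 0.35 * size * seq(1, 1 / steps, length.out = steps)
      for (k in seq_len(steps)) out[r <= radii[k]] <- k * height
      out
    },
    blobs = {
      ctr <- rbind(c(-0.22, -0.18), c(0.25, -0.1), c(-0.05, 0.24),
                   c(0.18, 0.2)) * size
      sd <- c(0.08, 0.055, 0.07, 0.045) * size
      out <- matrix(0, size, size)
      for (k in seq_len(nrow(ctr)))
        out <- out + exp(-((m - ctr[k, 1])^2 + (n - ctr[k, 2])^2) /
                           (2 * sd[k]^2))
      out / max(out) * height
    })
  phase_map(v, wrapped = FALSE)
}

#' Ground truth of a simulated acquisition
#'
#' Collects everything that defines a simulated non-telecentric off-axis
#' hologram: geometry, tilt, spherical wavefront, object phase/amplitude,
#' noise level and RNG seed. The spherical curvature can be given directly
#' (`C`) or through the optics (`f_TL`, `z`), related by
#' `C = f_TL^2 / (f_TL - z)`; `z == f_TL` is the telecentric limit.
#'
#' @param params an [acq_params()].
#' @param tilt a [tilt_angles()].
#' @param sphere a [spherical_wavefront()] (centre set, or defaulting to the
#'   image centre). Ignored when `f_TL` and `z` are supplied.
#' @param f_TL,z optional tube-lens focal length and stop-to-lens distance
#'   (micrometres) from which the curvature is derived.
#' @param object_phase unwrapped [phase_map()] or matrix (radians); default
#'   flat 0.
#' @param object_amplitude matrix in `[0, 1]`; default 1 everywhere.
#' @param noise_sd additive Gaussian intensity noise SD (default 0).
#' @param rng_seed integer seed controlling the noise realization.
#' @param pattern optional descriptor recorded in manifests, e.g.
#'   `list(kind = "star", size = 256, height = 2.15)`.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(params, tilt, sphere = NULL, f_TL = NULL,
                             z = NULL, object_phase = NULL,
                             object_amplitude = NULL, noise_sd = 0,
                             rng_seed = 1L, pattern = NULL) {
  stopifnot(inherits(params, "acq_params"), inherits(tilt, "tilt_angles"))
  dc <- dc_bins(params)
  if (!is.null(f_TL) && !is.null(z)) {
    if (isTRUE(all.equal(z, f_TL))) {
      sphere <- spherical_wavefront(telecentric = TRUE)
    } else {
      C <- f_TL^2 / (f_TL - z)
      sphere <- spherical_wavefront(abs(C), abs(C),
                                    h = dc[["u0"]], g = dc[["v0"]],
                                    sign = sign(C))
    }
  }
  if (is.null(sphere)) sphere <- spherical_wavefront(telecentric = TRUE)
  if (!sphere$telecentric && (!is.finite(sphere$h) || !is.finite(sphere$g)))
    sphere <- spherical_wavefront(sphere$C_x, sphere$C_y,
                                  h = dc[["u0"]], g = dc[["v0"]],
                                  sign = sphere$sign)
  op <- if (is.null(object_phase)) matrix(0, params$Y, params$X)
        else if (inherits(object_phase, "phase_map")) object_phase$values
        else as.matrix(object_phase)
  oa <- if (is.null(object_amplitude)) matrix(1, params$Y, params$X)
        else as.matrix(object_amplitude)
  if (!all(dim(op) == c(params$Y, params$X)) ||
      !all(dim(oa) == c(params$Y, params$X)))
    stop("object phase/amplitude shape must match params", call. = FALSE)
  if (min(oa) < 0 || max(oa) > 1)
    stop("object amplitude must lie in [0, 1]", call. = FALSE)
  structure(list(params = params, tilt = tilt, sphere = sphere,
                 f_TL = f_TL, z = z, object_phase = op,
                 object_amplitude = oa, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed), pattern = pattern),
            class = "simulation_truth")
}

#' Convenience: truth from carrier bin offsets and a pattern
#'
#' Builds a [simulation_truth()] from the spectral picture directly: carrier
#' offsets in bins (`u0 - P`, `v0 - Q`), curvature in micrometres, and a
#' [make_pattern()] descriptor.
#'
#' @param params an [acq_params()].
#' @param offset_bins numeric length-2, carrier offset `(u0 - P, v0 - Q)` in
#'   spectral bins.
#' @param C curvature in micrometres, or `NULL` for telecentric.
#' @param center sphere centre `c(h, g)` in 0-based pixels (default image
#'   centre).
#' @param sign converging (+1) or diverging (-1).
#' @param pattern pattern descriptor list or `NULL` for a flat object.
#' @param noise_sd,rng_seed see [simulation_truth()].
#' @return A `simulation_truth`.
#' @export
truth_from_bins <- function(params, offset_bins = c(0, 0), C = NULL,
                            center = NULL, sign = 1, pattern = NULL,
                            noise_sd = 0, rng_seed = 1L) {
  dc <- dc_bins(params)
  sx <- offset_bins[1] * params$wavelength / (params$X * params$delta_xy)
  sy <- offset_bins[2] * params$wavelength / (params$Y * params$delta_xy)
  tilt <- tilt_angles(asin(sx), asin(sy), params)
  sphere <- if (is.null(C)) {
    spherical_wavefront(telecentric = TRUE)
  } else {
    ctr <- center %||% c(dc[["u0"]], dc[["v0"]])
    spherical_wavefront(C, C, h = ctr[1], g = ctr[2], sign = sign)
  }
  op <- NULL
  if (!is.null(pattern)) {
    stopifnot(params$X == params$Y)
    op <- do.call(make_pattern, utils::modifyList(list(size = params$X),
                                                  pattern))
    pattern <- utils::modifyList(list(size = params$X), pattern)
  }
  simulation_truth(params, tilt, sphere = sphere, object_phase = op,
                   noise_sd = noise_sd, rng_seed = rng_seed,
                   pattern = pattern)
}

#' Simulate an off-axis non-telecentric hologram
#'
#' Samples `h = |u_IP + r|^2` on the sensor grid, with the image-plane field
#' `u_IP = a0 * exp(i * (phi0 + s))`, spherical phase
#' `s(m, n) = sign * pi/lambda * ((m-h)^2/C_x + (n-g)^2/C_y) * delta_xy^2`,
#' and plane reference `r = exp(i * t)` of unit amplitude with
#' `t(m, n) = 2*pi/lambda * ((m-u0) sin(theta_x) + (n-v0) sin(theta_y)) * delta_xy`.
#' Optional additive Gaussian intensity noise (clipped at 0) is reproducible
#' from `rng_seed`. The aperture stop is taken as infinite (no pupil
#' convolution).
#'
#' A carrier beyond the Nyquist limit raises an error naming the maximum
#' usable tilt; a +1-order support that overlaps the DC bin (no guard pixel)
#' raises a warning, since the spectral estimates then degrade gracefully
#' rather than fail.
#'
#' @param truth a [simulation_truth()].
#' @return A [hologram()].
#' @export
simulate_hologram <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  p <- truth$params
  dc <- dc_bins(p)
  sx <- sin(truth$tilt$theta_x); sy <- sin(truth$tilt$theta_y)
  lim <- p$wavelength / (2 * p$delta_xy)
  if (abs(sx) > lim || abs(sy) > lim)
    stop(sprintf(
      "aliasing: carrier exceeds Nyquist; max usable |sin theta| = %.5g (theta = %.5g rad)",
      lim, asin(min(1, lim))), call. = FALSE)
  if (!truth$sphere$telecentric) {
    Msup <- (p$X * p$delta_xy)^2 / (p$wavelength * abs(truth$sphere$C_x))
    Nsup <- (p$Y * p$delta_xy)^2 / (p$wavelength * abs(truth$sphere$C_y))
    offx <- abs(sx) * p$X * p$delta_xy / p$wavelength
    offy <- abs(sy) * p$Y * p$delta_xy / p$wavelength
    if (offx + Msup / 2 > p$X / 2 - 1 || offy + Nsup / 2 > p$Y / 2 - 1)
      warning("+1-order support reaches the spectrum edge; expect aliasing",
              call. = FALSE)
    else if (max(offx - Msup / 2, offy - Nsup / 2) < 1)
      warning("+1-order support overlaps the DC bin (no guard pixel)",
              call. = FALSE)
  }
  g <- pixel_grids(p)
  tphase <- 2 * pi / p$wavelength * p$delta_xy *
    ((g$m - dc[["u0"]]) * sx + (g$n - dc[["v0"]]) * sy)
  sphase <- if (truth$sphere$telecentric) 0 else {
    truth$sphere$sign * pi / p$wavelength * p$delta_xy^2 *
      ((g$m - truth$sphere$h)^2 / abs(truth$sphere$C_x) +
       (g$n - truth$sphere$g)^2 / abs(truth$sphere$C_y))
  }
  u <- truth$object_amplitude * exp(1i * (truth$object_phase + sphase))
  h <- Mod(u + exp(1i * tphase))^2
  if (truth$noise_sd > 0) {
    h <- with_local_seed(truth$rng_seed,
                         h + stats::rnorm(length(h), sd = truth$noise_sd))
    h <- pmax(h, 0)
    dim(h) <- c(p$Y, p$X)
  }
  hologram(h, p)
}

#' Write a ground-truth manifest as JSON
#'
#' Serializes every parameter of a [simulation_truth()] (geometry, tilt,
#' sphere, optics, noise SD, RNG seed and, when the object came from
#' [make_pattern()], its pattern descriptor) so the identical hologram can be
#' regenerated bit for bit. Telecentric curvature is written as the flag, not
#' a number. Free-form object arrays are not embedded; pattern-based truths
#' round-trip exactly.
#'
#' @param truth a [simulation_truth()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @seealso [read_truth_manifest()]
#' @export
write_truth_manifest <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  sp <- truth$sphere
  rec <- list(
    params = list(X = truth$params$X, Y = truth$params$Y,
                  delta_xy = truth$params$delta_xy,
                  wavelength = truth$params$wavelength),
    tilt = list(theta_x = truth$tilt$theta_x, theta_y = truth$tilt$theta_y),
    sphere = if (sp$telecentric) list(telecentric = TRUE)
             else list(telecentric = FALSE, C_x = sp$C_x, C_y = sp$C_y,
                       h = sp$h, g = sp$g, sign = sp$sign),
    f_TL = truth$f_TL, z = truth$z,
    noise_sd = truth$noise_sd, rng_seed = truth$rng_seed,
    pattern = truth$pattern)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a ground-truth manifest
#'
#' @param path JSON manifest written by [write_truth_manifest()].
#' @return A [simulation_truth()] (object arrays regenerated from the pattern
#'   descriptor when present, flat otherwise).
#' @export
read_truth_manifest <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- acq_params(rec$params$X, rec$params$Y, rec$params$delta_xy,
                       rec$params$wavelength)
  tilt <- tilt_angles(rec$tilt$theta_x, rec$tilt$theta_y)
  sphere <- if (isTRUE(rec$sphere$telecentric)) {
    spherical_wavefront(telecentric = TRUE)
  } else {
    spherical_wavefront(as.numeric(rec$sphere$C_x),
                        as.numeric(rec$sphere$C_y),
                        h = as.numeric(rec$sphere$h),
                        g = as.numeric(rec$sphere$g),
                        sign = as.numeric(rec$sphere$sign))
  }
  op <- NULL
  pattern <- rec$pattern
  if (!is.null(pattern) && length(pattern) > 0) {
    pattern <- as.list(pattern)
    op <- do.call(make_pattern, pattern)
  } else {
    pattern <- NULL
  }
  simulation_truth(params, tilt, sphere = sphere, object_phase = op,
                   noise_sd = rec$noise_sd %||% 0,
                   rng_seed = rec$rng_seed %||% 1L, pattern = pattern)
}
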