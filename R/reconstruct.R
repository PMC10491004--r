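# End-to-end reconstruction pipeline: spectrum -> +1 filtering -> tilt
# compensation -> spherical compensation (centre estimation, sign
# resolution, optional cost-driven refinement) -> optional unwrapping.

#' Reconstruct a quantitative phase image from one hologram
#'
#' Runs the full spectral-analysis pipeline:
#' [compute_spectrum()] -> ROI (supplied or [suggest_roi()]) ->
#' [filter_plus_one()] -> [tilt_from_roi()] -> [compensate_tilt()] ->
#' [curvature_from_roi()] -> [estimate_sphere_center()] (falling back to the
#' image centre with a warning) -> sign resolution -> optional
#' [optimize_sphere()] -> [compensate_sphere()] -> optional
#' [unwrap_phase()]. The amplitude image `a0 = |h_F|` is returned alongside
#' the phase, and every estimated parameter is recorded in a provenance
#' list.
#'
#' The converging/diverging ambiguity of the spherical wavefront (the
#' spectrum only gives curvature magnitudes) is resolved by compensating
#' with both signs and keeping the one with the lower phase standard
#' deviation ([cost_J2()]).
#'
#' @param holo a [hologram()].
#' @param roi a [spectrum_roi()], or `NULL` to auto-suggest.
#' @param telecentric logical; skip the spherical stage (plane wavefront).
#' @param sphere optional [spherical_wavefront()] overriding the spectral
#'   estimate (e.g. a seed known from calibration).
#' @param center optional `c(h, g)` overriding centre estimation.
#' @param optimize logical; run the cost-minimization refinement stage.
#' @param opt_control list of options for the refinement: `cost`
#'   ("J2"/"J1"), `algorithm` (default "ga_ps"), `bounds_fraction` (0.5),
#'   `ga_population` (15), `refine_center` (FALSE), `rng_seed` (1).
#' @param unwrap logical; also return the unwrapped phase.
#' @param dc_exclusion_radius passed to [suggest_roi()] when `roi` is NULL.
#' @return An object of class `dhm_reconstruction`: list with `phase`
#'   (wrapped [phase_map()]), `unwrapped` (or NULL), `amplitude` (matrix),
#'   `field` (tilt-compensated [complex_field()]), `roi`, `tilt`, `sphere`,
#'   `optimization` (or NULL) and `provenance`.
#' @export
reconstruct <- function(holo, roi = NULL, telecentric = FALSE, sphere = NULL,
                        center = NULL, optimize = FALSE,
                        opt_control = list(), unwrap = FALSE,
                        dc_exclusion_radius = NULL) {
  stopifnot(inherits(holo, "hologram"))
  p <- holo$params
  dc <- dc_bins(p)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  spec <- stage("compute_spectrum", compute_spectrum(holo))
  if (is.null(roi))
    roi <- stage("suggest_roi", suggest_roi(spec, dc_exclusion_radius))
  hF <- stage("filter_plus_one", filter_plus_one(spec, roi))
  tilt <- stage("tilt_from_roi", tilt_from_roi(roi, p))
  ft <- stage("compensate_tilt", compensate_tilt(hF, tilt))
  amplitude <- Mod(hF$values)

  opt <- NULL
  if (!is.null(sphere) && sphere$telecentric) telecentric <- TRUE
  if (telecentric) {
    sph <- spherical_wavefront(telecentric = TRUE)
    phase <- stage("compensate_sphere", compensate_sphere(ft, sph))
  } else {
    if (is.null(sphere)) {
      sph <- stage("curvature_from_roi", curvature_from_roi(roi, p))
    } else {
      sph <- sphere
    }
    ctr <- center
    if (is.null(ctr) && (!is.finite(sph$h) || !is.finite(sph$g))) {
      ctr <- tryCatch(
        estimate_sphere_center(phase_map(Arg(ft$values), wrapped = TRUE)),
        error = function(e) {
          warning(sprintf(
            "sphere centre estimation failed (%s); falling back to the image centre",
            conditionMessage(e)), call. = FALSE)
          c(h = dc[["u0"]], g = dc[["v0"]])
        })
    }
    if (!is.null(ctr))
      sph <- spherical_wavefront(sph$C_x, sph$C_y, h = ctr[1], g = ctr[2],
                                 sign = sph$sign)
    # resolve converging vs diverging: the wrong sign doubles the residual
    # ring frequency, so the mean wrapped phase gradient discriminates
    # robustly even when the seed curvature is off; J2 breaks near-ties
    sph_neg <- spherical_wavefront(sph$C_x, sph$C_y, h = sph$h, g = sph$g,
                                   sign = -sph$sign)
    grad_score <- function(v) {
      mean(abs(wrap_phase(v[, -1] - v[, -ncol(v)]))) +
        mean(abs(wrap_phase(v[-1, ] - v[-nrow(v), ])))
    }
    s_pos <- grad_score(compensate_sphere(ft, sph)$values)
    s_neg <- grad_score(compensate_sphere(ft, sph_neg)$values)
    if (s_neg < s_pos) sph <- sph_neg
    if (optimize) {
      oc <- utils::modifyList(list(cost = "J2", algorithm = "ga_ps",
                                   bounds_fraction = 0.5,
                                   ga_population = 15L,
                                   refine_center = FALSE, rng_seed = 1L),
                              opt_control)
      opt <- stage("optimize_sphere",
                   optimize_sphere(ft, sph, cost = oc$cost,
                                   algorithm = oc$algorithm,
                                   bounds_fraction = oc$bounds_fraction,
                                   ga_population = oc$ga_population,
                                   refine_center = oc$refine_center,
                                   rng_seed = oc$rng_seed))
      sph <- opt$best
    }
    phase <- stage("compensate_sphere", compensate_sphere(ft, sph))
  }

  unwrapped <- if (unwrap) stage("unwrap_phase", unwrap_phase(phase)) else NULL

  prov <- list(
    P = roi$P, Q = roi$Q, M = roi$M, N = roi$N,
    theta_x = tilt$theta_x, theta_y = tilt$theta_y,
    telecentric = telecentric || sph$telecentric,
    C_x = if (sph$telecentric) NULL else sph$C_x,
    C_y = if (sph$telecentric) NULL else sph$C_y,
    h = if (sph$telecentric) NULL else sph$h,
    g = if (sph$telecentric) NULL else sph$g,
    sign = if (sph$telecentric) NULL else sph$sign,
    optimized = !is.null(opt),
    cost = if (!is.null(opt)) opt$cost else NULL,
    algorithm = if (!is.null(opt)) opt$algorithm else NULL,
    cost_value = if (!is.null(opt)) opt$cost_value else NULL,
    evaluations = if (!is.null(opt)) opt$evaluations else NULL,
    rng_seed = if (!is.null(opt)) {
      utils::modifyList(list(rng_seed = 1L), opt_control)$rng_seed
    } else NULL,
    final_J2 = cost_J2(phase))

  structure(list(phase = phase, unwrapped = unwrapped, amplitude = amplitude,
                 field = ft, roi = roi, tilt = tilt, sphere = sph,
                 optimization = opt, provenance = prov),
            class = "dhm_reconstruction")
}

#' @export
print.dhm_reconstruction <- function(x, ...) {
  cat("<dhm_reconstruction>\n")
  print(x$roi); print(x$tilt); print(x$sphere)
  cat(sprintf("  final phase SD (J2): %.4g rad%s\n", x$provenance$final_J2,
              if (x$provenance$optimized) ", cost-refined" else ""))
  invisible(x)
}

#' @export
plot.dhm_reconstruction <- function(x, what = c("phase", "unwrapped",
                                                "amplitude"), ...) {
  what <- match.arg(what)
  if (what == "amplitude") {
    v <- t(x$amplitude)[, nrow(x$amplitude):1, drop = FALSE]
    graphics::image(v, asp = 1, axes = FALSE, main = "amplitude |h_F|",
                    col = grDevices::gray.colors(64), useRaster = TRUE, ...)
  } else {
    pm <- if (what == "unwrapped") x$unwrapped else x$phase
    if (is.null(pm)) stop("unwrapped phase was not computed", call. = FALSE)
    plot(pm, main = paste(what, "(rad)"), ...)
  }
  invisible(x)
}
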