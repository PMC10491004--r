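# Cost functions for residual-aberration minimization and image metrics.

#' Wrap-count cost J1
#'
#' A perfectly compensated wrapped phase map binarizes to an all-white image;
#' residual aberrations create dark fringes. J1 normalizes the phase to
#' `[0, 1]`, binarizes at Otsu's global threshold and counts the
#' below-threshold (non-white) pixels. A constant map returns 0 (the
#' degenerate all-white convention).
#'
#' @param phase a wrapped [phase_map()].
#' @return Non-negative integer count of non-white pixels.
#' @export
cost_J1 <- function(phase) {
  stopifnot(inherits(phase, "phase_map"))
  v <- phase$values
  rng <- range(v)
  if (rng[2] - rng[1] < 1e-9) return(0L)
  norm <- (v - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  sum(norm <= th)
}

#' Phase-spread cost J2
#'
#' Standard deviation of the wrapped phase values over all pixels. Smooth,
#' cheap, and in practice produces the most uniform background of the two
#' costs.
#'
#' @param phase a wrapped [phase_map()].
#' @return Non-negative scalar (radians).
#' @export
cost_J2 <- function(phase) {
  stopifnot(inherits(phase, "phase_map"))
  stats::sd(phase$values)
}

#' Structural similarity between two phase maps
#'
#' Mean SSIM with the standard constants (`K1 = 0.01`, `K2 = 0.03`, dynamic
#' range 1) over an 11 x 11 Gaussian window (`sigma = 1.5`). Both maps are
#' first affinely rescaled by their joint minimum and maximum so that they
#' share a common `[0, 1]` range; local statistics use circular boundary
#' handling.
#'
#' @param a,b [phase_map()]s (or plain matrices) of equal shape.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim_metric <- function(a, b) {
  av <- if (inherits(a, "phase_map")) a$values else as.matrix(a)
  bv <- if (inherits(b, "phase_map")) b$values else as.matrix(b)
  if (!all(dim(av) == dim(bv)))
    stop("SSIM requires equal shapes", call. = FALSE)
  lo <- min(av, bv); hi <- max(av, bv)
  if (hi - lo < 1e-12) return(1)
  x <- (av - lo) / (hi - lo)
  y <- (bv - lo) / (hi - lo)
  w <- outer(stats::dnorm(-5:5, sd = 1.5), stats::dnorm(-5:5, sd = 1.5))
  w <- w / sum(w)
  f <- function(z) EBImage::imageData(EBImage::filter2(EBImage::Image(z), w))
  c1 <- 0.01^2; c2 <- 0.03^2
  mx <- f(x); my <- f(y)
  sxx <- f(x * x) - mx^2
  syy <- f(y * y) - my^2
  sxy <- f(x * y) - mx * my
  smap <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(smap)
}
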