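# Core array containers. Matrices are stored with rows = y (index n, 0-based
# n = row - 1) and columns = x (index m, 0-based m = column - 1).

#' Complex field on the sensor grid
#'
#' A 2D complex array tied to its acquisition geometry. Used for both
#' image-plane fields and (centred) spectra.
#'
#' @param values complex matrix, `Y` rows x `X` columns.
#' @param params an [acq_params()] whose shape must match `values`.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, params) {
  stopifnot(inherits(params, "acq_params"))
  values <- as.matrix(values)
  if (!is.complex(values)) storage.mode(values) <- "complex"
  if (nrow(values) != params$Y || ncol(values) != params$X)
    stop(sprintf("field shape %d x %d does not match params %d x %d",
                 nrow(values), ncol(values), params$Y, params$X), call. = FALSE)
  structure(list(values = values, params = params), class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d px\n", x$params$Y, x$params$X))
  invisible(x)
}

#' @export
as.matrix.complex_field <- function(x, ...) x$values

#' Phase map in radians
#'
#' @param values real matrix of phase values in radians.
#' @param wrapped logical; `TRUE` means all values lie in `(-pi, pi]`.
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(values, wrapped = TRUE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("phase values must be numeric", call. = FALSE)
  if (wrapped) {
    r <- range(values, finite = TRUE)
    if (r[1] <= -pi - 1e-9 || r[2] > pi + 1e-9)
      stop("wrapped phase must lie in (-pi, pi]", call. = FALSE)
  }
  structure(list(values = values, wrapped = isTRUE(wrapped)),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px, %s, range [%.3f, %.3f] rad\n",
              nrow(x$values), ncol(x$values),
              if (x$wrapped) "wrapped" else "unwrapped",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.matrix.phase_map <- function(x, ...) x$values

#' @export
plot.phase_map <- function(x, main = NULL, ...) {
  v <- t(x$values)[, nrow(x$values):1, drop = FALSE]
  graphics::image(v, asp = nrow(x$values) / ncol(x$values), axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = main %||% "phase (rad)", useRaster = TRUE, ...)
  invisible(x)
}

#' Recorded hologram intensity
#'
#' @param values real non-negative matrix of intensities, `Y` rows x `X`
#'   columns.
#' @param params an [acq_params()] matching the array shape.
#' @return An object of class `hologram`.
#' @export
hologram <- function(values, params) {
  stopifnot(inherits(params, "acq_params"))
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop("hologram contains NaN/Inf pixels", call. = FALSE)
  if (any(values < 0))
    stop("hologram intensities must be non-negative", call. = FALSE)
  if (nrow(values) != params$Y || ncol(values) != params$X)
    stop(sprintf("hologram shape %d x %d does not match params %d x %d",
                 nrow(values), ncol(values), params$Y, params$X), call. = FALSE)
  structure(list(values = values, params = params), class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d px, intensity range [%.3g, %.3g]\n",
              x$params$Y, x$params$X, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.matrix.hologram <- function(x, ...) x$values

#' Wrap phase values to (-pi, pi]
#'
#' @param x numeric vector/matrix of phase values in radians.
#' @return Values folded into the principal interval `(-pi, pi]`, same shape.
#' @export
wrap_phase <- function(x) {
  -((-x + pi) %% (2 * pi) - pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based pixel index grids: m = column index, n = row index.
pixel_grids <- function(params) {
  list(m = matrix(0:(params$X - 1L), params$Y, params$X, byrow = TRUE),
       n = matrix(0:(params$Y - 1L), params$Y, params$X))
}

#' Circular standard deviation of a set of angles
#'
#' `sqrt(-2 log |R|)` where `R` is the mean resultant vector of
#' `exp(i * x)`. Invariant under a common offset, which makes it the right
#' spread measure for wrapped phase differences.
#'
#' @param x angles in radians (any shape).
#' @return Non-negative scalar, radians.
#' @export
circular_sd <- function(x) {
  r <- Mod(mean(exp(1i * x)))
  sqrt(pmax(0, -2 * log(pmin(1, r))))
}
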