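# File input/output: holograms from TIFF/PNG, phase/amplitude/spectrum
# export, provenance JSON.

#' Read a hologram from a TIFF or PNG file
#'
#' Accepts single-channel 8/16-bit integer or float images; multi-channel
#' images are averaged to one channel. Values are used as recorded (readTIFF
#' and readPNG rescale integer data to `[0, 1]`, which is harmless: the
#' method is invariant to a global intensity scale).
#'
#' @param path image file, extension `.tif`/`.tiff` or `.png`.
#' @param delta_xy pixel pitch in micrometres.
#' @param wavelength wavelength in micrometres.
#' @return A [hologram()].
#' @export
read_hologram <- function(path, delta_xy, wavelength) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported hologram format '.%s' (use TIFF or PNG)", ext),
         call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  hologram(img, acq_params(ncol(img), nrow(img), delta_xy, wavelength))
}

#' Write a matrix as a 32-bit TIFF, rescaled to [0, 1]
#'
#' `writeTIFF` stores samples in `[0, 1]`, so the values are affinely
#' rescaled and the original range is returned (and, if `sidecar` is TRUE,
#' written next to the file as JSON) so the map can be restored exactly.
#'
#' @param values numeric matrix (e.g. phase in radians).
#' @param path output `.tif` path.
#' @param sidecar write `<path>.json` with the range (default TRUE).
#' @return Invisibly, `c(min, max)` of the original values.
#' @export
write_scaled_tiff <- function(values, path, sidecar = TRUE) {
  values <- as.matrix(values)
  rng <- range(values)
  scl <- if (diff(rng) > 0) (values - rng[1]) / diff(rng)
         else values * 0
  tiff::writeTIFF(scl, path, bits.per.sample = 32L)
  if (sidecar)
    jsonlite::write_json(list(min = rng[1], max = rng[2]),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(rng)
}

#' Read back a matrix written by [write_scaled_tiff()]
#'
#' @param path the `.tif` path (its `.json` sidecar must exist).
#' @return Numeric matrix on the original scale.
#' @export
read_scaled_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  rng <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img * (rng$max - rng$min) + rng$min
}

#' Write an 8-bit preview PNG of a matrix
#'
#' @param values numeric matrix.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_preview_png <- function(values, path) {
  values <- as.matrix(values)
  rng <- range(values)
  scl <- if (diff(rng) > 0) (values - rng[1]) / diff(rng) else values * 0
  png::writePNG(scl, path)
  invisible(path)
}

#' Export the log-magnitude spectrum for inspection
#'
#' @param spectrum a centred spectrum ([complex_field()]).
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tiff <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "complex_field"))
  write_scaled_tiff(log1p(Mod(spectrum$values)), path)
  invisible(path)
}

#' Write the provenance record of a reconstruction as JSON
#'
#' @param recon a `dhm_reconstruction` (see [reconstruct()]).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(recon, path) {
  stopifnot(inherits(recon, "dhm_reconstruction"))
  jsonlite::write_json(recon$provenance, path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
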