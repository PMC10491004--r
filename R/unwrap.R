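#' Two-dimensional phase unwrapping
#'
#' Reliability-sorting unwrapper: pixel reliabilities are computed from
#' wrapped second differences, and pixels are merged along edges in
#' decreasing reliability order, each merge adding the integer multiple of
#' `2*pi` that makes neighbouring pixels differ by their wrapped gradient.
#' The output is congruent to the input modulo `2*pi` at every pixel and
#' continuous along any path within a simply connected noiseless region. The
#' global offset is fixed by anchoring the minimum output value near the
#' minimum input value (piston is arbitrary in interferometry).
#'
#' @param phase a wrapped [phase_map()].
#' @return An unwrapped [phase_map()] (`wrapped = FALSE`).
#' @examples
#' p <- acq_params(64, 64, 5.86, 0.532)
#' ramp <- matrix(seq(0, 6 * pi, length.out = 64), 64, 64, byrow = TRUE)
#' u <- unwrap_phase(phase_map(wrap_phase(ramp)))
#' @export
unwrap_phase <- function(phase) {
  stopifnot(inherits(phase, "phase_map"))
  if (!phase$wrapped) return(phase)
  out <- unwrap2d_cpp(phase$values)
  # remove the accumulated global 2*pi offset, keeping congruence
  k <- round(stats::median(out - phase$values) / (2 * pi))
  phase_map(out - 2 * pi * k, wrapped = FALSE)
}
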