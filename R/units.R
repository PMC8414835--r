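# Unit conversions. Geometry is handled in clinical units (mm); the FEM and
# hemodynamics solvers work in SI (Pa, m, m^3/s) and convert at their
# boundaries.

#' Unit conversion helpers
#'
#' The package exposes clinical units at every user-facing boundary
#' (mmHg for pressure, mm for length, mL/s and L/min for flow) and converts
#' to SI internally. One mmHg is taken as 133.322 Pa.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @name units
NULL

MMHG_PA <- 133.322

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * MMHG_PA

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / MMHG_PA

#' @rdname units
#' @export
lmin_to_m3s <- function(x) x * 1e-3 / 60

#' @rdname units
#' @export
m3s_to_mls <- function(x) x * 1e6

#' @rdname units
#' @export
mls_to_m3s <- function(x) x * 1e-6
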