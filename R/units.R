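#' Unit conversions at the package interfaces
#'
#' Geometry is specified in millimetres, flows in mL/min and pressures in
#' mmHg at the user-facing interfaces; all physics is computed in SI
#' (m, m^3/s, Pa) internally. These helpers are exported so scripts can
#' convert explicitly rather than guessing.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mlmin_to_m3s <- function(x) x * 1e-6 / 60

#' @rdname units
#' @export
m3s_to_mlmin <- function(x) x * 60 * 1e6

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * 133.322387415

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / 133.322387415

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3
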