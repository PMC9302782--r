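#' Vessel and anastomosis specifications
#'
#' `vessel_spec` describes one vessel of the graft circuit: its lumen
#' diameter and how far it extends on either side of its anastomosis,
#' expressed as multiples of the diameter. The defaults follow the
#' clinical parametrization used throughout the package: artery 6.6 mm,
#' vein 7.7 mm, graft 6 mm; host vessels trimmed to 7.5 diameters on the
#' proximal side and 3.25 diameters on the distal side of the anastomosis
#' (before flow extensions double those lengths).
#'
#' @param label one of `"artery"`, `"vein"`, `"graft"`.
#' @param diameter lumen diameter, mm.
#' @param proximal_multiple,distal_multiple trimmed segment length on each
#'   side of the anastomosis, in diameters (ignored for the graft).
#' @return an object of class `avg_vessel_spec`.
#' @export
vessel_spec <- function(label = c("artery", "vein", "graft"), diameter,
                        proximal_multiple = 7.5, distal_multiple = 3.25) {
  label <- match.arg(label)
  check_positive(diameter, "diameter")
  check_nonnegative(proximal_multiple, "proximal_multiple")
  check_nonnegative(distal_multiple, "distal_multiple")
  structure(list(label = label, diameter = diameter,
                 proximal_multiple = proximal_multiple,
                 distal_multiple = distal_multiple),
            class = "avg_vessel_spec")
}

#' @rdname vessel_spec
#' @export
default_vessel_specs <- function() {
  list(artery = vessel_spec("artery", 6.6),
       vein   = vessel_spec("vein", 7.7),
       graft  = vessel_spec("graft", 6.0))
}

#' @param angle anastomotic angle between graft and host vessel, degrees,
#'   in (0, 180).
#' @param in_plane logical; graft approach lies in the host-vessel plane.
#' @rdname vessel_spec
#' @export
anastomosis_spec <- function(angle = 45, in_plane = TRUE) {
  if (!is.numeric(angle) || length(angle) != 1L || !is.finite(angle) ||
      angle <= 0 || angle >= 180)
    stopf("'angle' must lie strictly between 0 and 180 degrees")
  structure(list(angle = angle, in_plane = isTRUE(in_plane)),
            class = "avg_anastomosis_spec")
}

as_spec_list <- function(specs) {
  if (inherits(specs, "avg_vessel_spec")) specs <- list(specs)
  labs <- vapply(specs, function(s) s$label, character(1))
  stats::setNames(specs, labs)
}
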