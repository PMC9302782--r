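#' Wall-shear-stress field time-series
#'
#' Per-sample-point WSS vectors on a uniform time grid spanning one
#' cardiac cycle. The grid is half-open: `n_t` samples cover `[0, T)` and
#' all cycle integrals use the trapezoidal rule with periodic wrap (which,
#' on a uniform periodic grid, reduces to the sample mean times `T`).
#'
#' @param tau numeric array `n_t x n_p x 3`: WSS vectors, Pa.
#' @param areas per-point surface areas, m^2 (length `n_p`).
#' @param period cycle duration `T`, s.
#' @param points optional `n_p x 3` sample-point coordinates, mm.
#' @return object of class `avg_wss_field`.
#' @export
wss_field_series <- function(tau, areas, period, points = NULL) {
  if (length(dim(tau)) != 3L || dim(tau)[3] != 3L)
    stopf("'tau' must be an n_t x n_p x 3 array of WSS vectors")
  if (dim(tau)[1] < 8L)
    stopf("need at least 8 time samples per cycle")
  if (length(areas) != dim(tau)[2])
    stopf("'areas' length must match the number of sample points")
  if (any(areas <= 0)) stopf("all point areas must be positive")
  check_positive(period, "period")
  structure(list(tau = tau, areas = areas, period = period,
                 points = points),
            class = "avg_wss_field")
}

#' @export
print.avg_wss_field <- function(x, ...) {
  cat(sprintf("<avg_wss_field> %d points x %d time samples, T = %.3g s\n",
              dim(x$tau)[2], dim(x$tau)[1], x$period))
  invisible(x)
}

#' Velocity-magnitude field time-series
#'
#' @param u numeric matrix `n_t x n_p`: velocity magnitudes, m/s, on a
#'   uniform half-open time grid over one cycle.
#' @param period cycle duration, s.
#' @param points optional `n_p x 3` coordinates, mm.
#' @return object of class `avg_velocity_field`.
#' @export
velocity_field_series <- function(u, period, points = NULL) {
  if (!is.matrix(u)) stopf("'u' must be an n_t x n_p matrix")
  if (any(!is.finite(u))) stopf("velocity series contains non-finite values")
  check_positive(period, "period")
  structure(list(u = u, period = period, points = points),
            class = "avg_velocity_field")
}

tau_component <- function(field, k) {
  d <- dim(field$tau)
  matrix(field$tau[, , k], d[1], d[2])   # keep matrix shape at n_p = 1
}

tau_magnitude <- function(field) {
  sqrt(tau_component(field, 1)^2 + tau_component(field, 2)^2 +
         tau_component(field, 3)^2)
}

#' Time-averaged WSS magnitude
#'
#' `TAWSS = (1/T) int_0^T |tau(t)| dt` per sample point (trapezoidal rule
#' with periodic wrap).
#'
#' @param field an [wss_field_series()].
#' @return numeric vector, Pa, one value per point.
#' @export
tawss <- function(field) {
  stopifnot(inherits(field, "avg_wss_field"))
  colMeans(tau_magnitude(field))
}

#' Peak WSS magnitude over the cycle
#'
#' `WSS_max = max_t |tau(t)|` per sample point.
#'
#' @param field an [wss_field_series()].
#' @return numeric vector, Pa.
#' @export
wss_max <- function(field) {
  stopifnot(inherits(field, "avg_wss_field"))
  apply(tau_magnitude(field), 2L, max)
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 (1 - |int tau dt| / int |tau| dt)` per point: 0 for
#' unidirectional WSS, 0.5 for purely oscillatory WSS (zero-mean vector).
#' Points with zero total shear (`int |tau| dt = 0`) have no defined OSI;
#' they are returned as `NA` and excluded from area fractions by the
#' callers (their count is reported by [metric_summary()]).
#'
#' @param field an [wss_field_series()].
#' @return numeric vector in `[0, 0.5]`, `NA` where undefined.
#' @export
osi <- function(field) {
  stopifnot(inherits(field, "avg_wss_field"))
  num <- sqrt(colMeans(tau_component(field, 1))^2 +
                colMeans(tau_component(field, 2))^2 +
                colMeans(tau_component(field, 3))^2)
  den <- colMeans(tau_magnitude(field))
  out <- 0.5 * (1 - num / den)
  out[den == 0] <- NA_real_
  pmin(pmax(out, 0), 0.5)
}

#' Region mask over field sample points
#'
#' @param select logical vector (one flag per sample point).
#' @param descriptor free-text description of the region.
#' @return object of class `avg_region_mask`.
#' @export
region_mask <- function(select, descriptor = "custom") {
  if (!is.logical(select)) stopf("'select' must be logical")
  if (!any(select)) stopf("empty region mask ('%s')", descriptor)
  structure(list(select = select, descriptor = descriptor),
            class = "avg_region_mask")
}

#' Perianastomotic region mask
#'
#' Selects the venous sample points whose arc-length coordinate lies in a
#' window around the venous anastomosis: from 2.5 cm distal to 3.0 cm
#' proximal by default. The arc-length sign convention is distal negative,
#' proximal positive, anastomosis at 0; the window is a closed interval,
#' so points exactly on a bound are included.
#'
#' @param surf an [surface_geometry()] built by [sweep_and_join()] (its
#'   vertices carry branch provenance and centerline arc coordinates).
#' @param tree the [centerline_tree()] the surface was swept from.
#' @param distal,proximal window extent on each side of the anastomosis,
#'   mm.
#' @param points optional `n x 3` matrix of field sample points, mm; when
#'   given, each is mapped to the vein by nearest-vertex projection and
#'   the mask is over these points instead of the surface vertices.
#' @return an [region_mask()] over the surface vertices (or `points`).
#' @export
perianastomotic_mask <- function(surf, tree, distal = 25, proximal = 30,
                                 points = NULL) {
  jv <- tree$junctions$venous
  if (is.null(jv)) stopf("geometry lacks a venous junction")
  if (distal + proximal <= 0)
    stopf("empty perianastomotic window")
  if (is.null(surf$vertex_branch))
    stopf("surface lacks vertex branch provenance")
  s_rel <- surf$vertex_s - jv$host_s    # vein ordered distal -> proximal
  on_vein <- surf$vertex_branch == "vein"
  sel_v <- on_vein & s_rel >= -distal & s_rel <= proximal
  if (is.null(points))
    return(region_mask(sel_v, sprintf(
      "venous perianastomotic [-%g, +%g] mm", distal, proximal)))
  vid <- vapply(seq_len(nrow(points)), function(i)
    which.min(colSums((t(surf$vertices) - points[i, ])^2)), integer(1))
  region_mask(sel_v[vid], sprintf(
    "venous perianastomotic [-%g, +%g] mm (projected)", distal, proximal))
}

#' Area-weighted threshold fraction
#'
#' Percentage of the masked area on which `predicate` holds:
#' `100 * area(predicate & mask) / area(mask)`. `NA` values (e.g.
#' undefined OSI) are excluded from both numerator and denominator.
#'
#' @param values numeric vector, one value per sample point.
#' @param areas per-point areas, m^2 (or any consistent unit).
#' @param predicate function mapping values to logical, e.g.
#'   `function(x) x > 0.25`.
#' @param mask an [region_mask()] or `NULL` for all points.
#' @return percentage in `[0, 100]`.
#' @export
area_fraction <- function(values, areas, predicate, mask = NULL) {
  sel <- if (is.null(mask)) rep(TRUE, length(values)) else mask$select
  if (!any(sel)) stopf("empty mask")
  ok <- sel & !is.na(values)
  denom <- sum(areas[ok])
  if (denom == 0) stopf("mask selects zero area")
  100 * sum(areas[ok & predicate(values)]) / denom
}

#' Disturbed-WSS thresholds
#'
#' The four exposure bands used throughout: non-physiologically low TAWSS
#' (< 0.1 Pa), high peak WSS (> 7 Pa and <= 40 Pa, a half-open band),
#' very high peak WSS (> 40 Pa, endothelial-damage level) and highly
#' oscillatory WSS (OSI > 0.25).
#'
#' @return named list of threshold values.
#' @export
wss_thresholds <- function() {
  list(tawss_low = 0.1, wss_high = 7, wss_very_high = 40, osi_high = 0.25)
}

#' Summarise disturbed-WSS exposure over regions
#'
#' Computes TAWSS, peak WSS and OSI on the field and reports, per region,
#' the area percentages exposed to each disturbed-WSS band of
#' [wss_thresholds()]. `WSS_high` is the band (7, 40] Pa and
#' `WSS_very_high` the exceedance (40, Inf) Pa, so the two are disjoint.
#'
#' @param field an [wss_field_series()].
#' @param regions named list of [region_mask()]s (`NULL` entry = all
#'   points).
#' @param thresholds list as returned by [wss_thresholds()].
#' @return object of class `avg_metric_summary`: a data frame of area
#'   fractions (%) per region plus a QC attribute with the count of
#'   undefined-OSI points.
#' @export
metric_summary <- function(field, regions = list(total = NULL),
                           thresholds = wss_thresholds()) {
  ta <- tawss(field); wm <- wss_max(field); os <- osi(field)
  th <- thresholds
  rows <- lapply(names(regions), function(nm) {
    m <- regions[[nm]]
    data.frame(
      region = nm,
      WSS_low = area_fraction(ta, field$areas,
                              function(x) x < th$tawss_low, m),
      WSS_high = area_fraction(wm, field$areas,
                               function(x) x > th$wss_high &
                                 x <= th$wss_very_high, m),
      WSS_very_high = area_fraction(wm, field$areas,
                                    function(x) x > th$wss_very_high, m),
      OSI_high = area_fraction(os, field$areas,
                               function(x) x > th$osi_high, m))
  })
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- th
  attr(out, "n_undefined_osi") <- sum(is.na(os))
  class(out) <- c("avg_metric_summary", "data.frame")
  out
}

#' @export
print.avg_metric_summary <- function(x, ...) {
  cat("<avg_metric_summary> area fractions (%)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  n_na <- attr(x, "n_undefined_osi")
  if (n_na > 0)
    cat(sprintf("  QC: %d point(s) with undefined OSI excluded\n", n_na))
  invisible(x)
}

#' Vertex areas of a triangulated surface
#'
#' One third of the area of each adjacent triangle is attributed to every
#' vertex, so vertex areas sum exactly to the surface area. Returned in
#' m^2 (surface coordinates are mm).
#'
#' @param surf an [surface_geometry()].
#' @param wall_only count only faces labelled `wall`.
#' @return numeric vector, m^2, one value per vertex.
#' @export
vertex_areas <- function(surf, wall_only = TRUE) {
  keep <- if (wall_only) surf$face_labels == "wall"
  else rep(TRUE, nrow(surf$faces))
  va <- numeric(nrow(surf$vertices))
  f <- surf$faces[keep, , drop = FALSE]
  a3 <- rep(surf$face_areas[keep] / 3, 3L)
  idx <- as.vector(f)
  for (k in seq_along(idx)) va[idx[k]] <- va[idx[k]] + a3[k]
  va * 1e-6                              # mm^2 -> m^2
}
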