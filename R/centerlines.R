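#' Centerline trees
#'
#' A centerline tree holds the three labelled, arc-length parameterized
#' branch polylines of a graft circuit (artery, vein, graft) plus the two
#' anastomosis reference points. Coordinates are millimetres. Conventions
#' (documented and stable): right-handed axes; for the idealized build the
#' artery runs along +x with its anastomosis at the origin and the vein is
#' parallel at `y = loop_width`; branch point order follows the flow
#' direction (artery: inlet to outlet; vein: distal inlet to proximal
#' outlet; graft: arterial to venous anastomosis).
#'
#' @param branches named list (`artery`, `vein`, `graft`), each a list
#'   with `points` (n x 3 matrix, mm), `arc` (cumulative arc length, mm)
#'   and `radius` (per-point lumen radius, mm).
#' @param junctions named list (`arterial`, `venous`), each a list with
#'   `point` (xyz), `host` (branch label), `host_s` and `graft_s`
#'   (arc-length coordinates of the reference on host and graft).
#' @param spacing resampling spacing used to build the branches, mm.
#' @return an object of class `avg_centerline_tree`.
#' @export
centerline_tree <- function(branches, junctions, spacing = 0.25) {
  for (nm in names(branches)) {
    b <- branches[[nm]]
    if (is.null(b$points) || nrow(b$points) < 2L)
      stopf("branch '%s' is degenerate", nm)
    if (any(diff(b$arc) <= 0))
      stopf("arc length must be strictly increasing along branch '%s'", nm)
    if (any(b$radius <= 0))
      stopf("branch '%s' has non-positive radii", nm)
  }
  structure(list(branches = branches, junctions = junctions,
                 spacing = spacing),
            class = "avg_centerline_tree")
}

#' @export
print.avg_centerline_tree <- function(x, ...) {
  cat("<avg_centerline_tree>\n")
  for (nm in names(x$branches)) {
    b <- x$branches[[nm]]
    cat(sprintf("  %-6s %5d pts, length %7.2f mm, radius %.2f mm\n",
                nm, nrow(b$points), max(b$arc), b$radius[1]))
  }
  for (nm in names(x$junctions)) {
    j <- x$junctions[[nm]]
    cat(sprintf("  %s anastomosis at (%.2f, %.2f, %.2f) mm\n",
                nm, j$point[1], j$point[2], j$point[3]))
  }
  invisible(x)
}

make_branch <- function(points, radius, spacing) {
  rs <- resample_polyline(points, spacing)
  list(points = rs$points, arc = rs$arc,
       radius = rep(radius, nrow(rs$points)))
}

# Evaluate a cubic Bezier at parameter values u in [0,1].
bezier3 <- function(p0, p1, p2, p3, u) {
  b <- cbind((1 - u)^3, 3 * u * (1 - u)^2, 3 * u^2 * (1 - u), u^3)
  b %*% rbind(p0, p1, p2, p3)
}

#' Build idealized graft-circuit centerlines
#'
#' Constructs the idealized configuration: straight artery and vein,
#' joined by a smooth planar graft loop that meets each host vessel at the
#' specified anastomotic angle. Host branch lengths on each side of the
#' anastomosis equal `multiple * diameter` from the vessel specs (the
#' pre-extension lengths; [trim_and_extend()] doubles them with straight
#' flow extensions). The graft path is a cubic Bezier whose endpoint
#' tangents realise the anastomotic angles exactly; its bulge is
#' controlled by `graft_path`.
#'
#' @param specs list of [vessel_spec()]s for artery, vein and graft (see
#'   [default_vessel_specs()]).
#' @param anastomoses named list with `arterial` and `venous`
#'   [anastomosis_spec()]s.
#' @param graft_path list of loop-shape controls: `loop_width` (artery to
#'   vein axis distance, mm), `venous_offset` (x-offset of the venous
#'   anastomosis, mm), `control_fraction` (Bezier control-point distance
#'   as a fraction of the anastomosis separation), `out_of_plane` (z
#'   amplitude of the interior control points, mm; forced to 0 when both
#'   anastomoses are declared in-plane).
#' @param spacing resampling spacing, mm.
#' @return an [centerline_tree()].
#' @examples
#' tree <- build_idealized_centerlines()
#' measure_anastomosis_angle(tree, "venous")  # ~45 degrees
#' @export
build_idealized_centerlines <- function(specs = default_vessel_specs(),
                                        anastomoses = list(
                                          arterial = anastomosis_spec(45),
                                          venous = anastomosis_spec(45)),
                                        graft_path = list(),
                                        spacing = 0.25) {
  specs <- as_spec_list(specs)
  for (nm in c("artery", "vein", "graft"))
    if (is.null(specs[[nm]])) stopf("missing vessel spec '%s'", nm)
  gp <- utils::modifyList(list(loop_width = 40, venous_offset = 0,
                               control_fraction = 0.45, out_of_plane = 0),
                          graft_path)
  th_a <- anastomoses$arterial$angle * pi / 180
  th_v <- anastomoses$venous$angle * pi / 180
  in_plane <- anastomoses$arterial$in_plane && anastomoses$venous$in_plane
  if (in_plane) gp$out_of_plane <- 0

  sa <- specs$artery; sv <- specs$vein; sg <- specs$graft
  A <- c(0, 0, 0)                                   # arterial anastomosis
  V <- c(gp$venous_offset, gp$loop_width, 0)        # venous anastomosis
  if (vec_norm(V - A) < 1e-9)
    stopf("impossible loop: graft endpoints coincide")

  # Straight hosts along +x. Pre-extension lengths: multiple * diameter.
  La_p <- sa$proximal_multiple * sa$diameter
  La_d <- sa$distal_multiple * sa$diameter
  Lv_p <- sv$proximal_multiple * sv$diameter
  Lv_d <- sv$distal_multiple * sv$diameter
  artery_pts <- rbind(A - c(La_p, 0, 0), A, A + c(La_d, 0, 0))
  vein_pts   <- rbind(V - c(Lv_d, 0, 0), V, V + c(Lv_p, 0, 0))

  # Graft leaves the artery and arrives at the vein at the requested
  # angles to the host flow direction (+x), approaching the vein from the
  # arterial side (+y component at both ends).
  d_a <- c(cos(th_a), sin(th_a), 0)
  d_v <- c(cos(th_v), sin(th_v), 0)
  cdist <- gp$control_fraction * vec_norm(V - A)
  p1 <- A + cdist * d_a + c(0, 0, gp$out_of_plane)
  p2 <- V - cdist * d_v + c(0, 0, gp$out_of_plane)
  u <- seq(0, 1, length.out = 600L)
  graft_pts <- bezier3(A, p1, p2, V, u)

  branches <- list(
    artery = make_branch(artery_pts, sa$diameter / 2, spacing),
    vein   = make_branch(vein_pts, sv$diameter / 2, spacing),
    graft  = make_branch(graft_pts, sg$diameter / 2, spacing))

  g_len <- max(branches$graft$arc)
  junctions <- list(
    arterial = list(point = A, host = "artery", host_s = La_p, graft_s = 0),
    venous   = list(point = V, host = "vein", host_s = Lv_d,
                    graft_s = g_len))
  centerline_tree(branches, junctions, spacing)
}

branch_tangent <- function(branch, s, window = 1.0) {
  # Direction of increasing arc length at coordinate s. Interior points
  # use a central secant over +/- window; near a branch end a one-sided
  # second-order difference cancels the leading curvature bias.
  arc <- branch$arc
  n <- length(arc)
  if (n < 3L) {
    if (n < 2L) stopf("tangent undefined: too few points")
    return(unit_vec(branch$points[2L, ] - branch$points[1L, ]))
  }
  at <- function(si) {
    i <- findInterval(si, arc, all.inside = TRUE)
    w <- (si - arc[i]) / (arc[i + 1] - arc[i])
    (1 - w) * branch$points[i, ] + w * branch$points[i + 1, ]
  }
  lo <- arc[1]; hi <- arc[n]
  if (s - lo < window) {
    h <- min(window, (hi - lo) / 2)
    p0 <- at(lo); p1 <- at(lo + h); p2 <- at(lo + 2 * h)
    return(unit_vec(4 * (p1 - p0) - (p2 - p0)))
  }
  if (hi - s < window) {
    h <- min(window, (hi - lo) / 2)
    p0 <- at(hi); p1 <- at(hi - h); p2 <- at(hi - 2 * h)
    return(unit_vec(-(4 * (p1 - p0) - (p2 - p0))))
  }
  unit_vec(at(min(hi, s + window)) - at(max(lo, s - window)))
}

#' Measure an anastomotic angle on a centerline tree
#'
#' Returns the angle, in degrees, between the graft flow direction and the
#' host-vessel flow direction at the requested anastomosis. Angles at the
#' 0/180 degree boundary (graft collinear with the host) are reported with
#' a warning since the junction is geometrically degenerate there.
#'
#' @param tree an [centerline_tree()].
#' @param which `"arterial"` or `"venous"`.
#' @param window secant half-width used for tangent estimation, mm.
#' @return angle in degrees, in (0, 180).
#' @export
measure_anastomosis_angle <- function(tree, which = c("arterial", "venous"),
                                      window = 0.5) {
  which <- match.arg(which)
  j <- tree$junctions[[which]]
  if (is.null(j)) stopf("tree has no %s junction", which)
  host <- tree$branches[[j$host]]
  graft <- tree$branches$graft
  t_host <- branch_tangent(host, j$host_s, window)
  # Graft flow direction adjacent to this junction.
  t_graft <- if (which == "arterial")
    branch_tangent(graft, min(graft$arc), window)
  else
    branch_tangent(graft, max(graft$arc), window)
  ang <- angle_between(t_graft, t_host)
  if (ang < 1 || ang > 179)
    warning(sprintf("graft nearly collinear with host (%.2f deg)", ang))
  ang
}

# Sub-polyline of a branch from arc s0 towards s1 (either order),
# starting exactly at s0 and trimmed exactly at s1.
slice_branch <- function(branch, s0, s1) {
  arc <- branch$arc
  interp_at <- function(s) {
    i <- findInterval(s, arc, all.inside = TRUE)
    w <- (s - arc[i]) / (arc[i + 1] - arc[i])
    (1 - w) * branch$points[i, ] + w * branch$points[i + 1, ]
  }
  lo <- min(s0, s1); hi <- max(s0, s1)
  inside <- which(arc > lo + 1e-9 & arc < hi - 1e-9)
  pts <- rbind(interp_at(lo), branch$points[inside, , drop = FALSE],
               interp_at(hi))
  if (s0 > s1) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  pts
}

# Straight tangent-continuous extension of a junction-anchored side
# polyline (ordered junction -> outward) by `extra` mm.
extend_side <- function(pts, extra, spacing) {
  n <- nrow(pts)
  if (extra <= 0 || n < 2L) return(pts)
  tang <- unit_vec(pts[n, ] - pts[n - 1L, ])
  steps <- seq(spacing, extra, by = spacing)
  if (length(steps) == 0L || abs(steps[length(steps)] - extra) > 1e-9)
    steps <- c(steps, extra)
  ext <- matrix(pts[n, ], length(steps), 3, byrow = TRUE) +
    outer(steps, tang)
  rbind(pts, ext)
}

#' Trim host vessels and add straight flow extensions
#'
#' Each host branch (artery and vein) is measured from its anastomosis
#' reference, cut to `proximal_multiple * diameter` on the proximal side
#' and `distal_multiple * diameter` on the distal side, and then a
#' straight, tangent-continuous flow extension doubles each side. Flow
#' extensions distance boundary artefacts from the anastomosis without
#' altering the region of interest. The graft is untouched. The operation
#' is idempotent: re-applying it re-cuts to the same lengths and rebuilds
#' identical extensions.
#'
#' @param tree an [centerline_tree()] with junctions located.
#' @param specs vessel specs providing diameters and multiples.
#' @return a new [centerline_tree()].
#' @export
trim_and_extend <- function(tree, specs = default_vessel_specs()) {
  specs <- as_spec_list(specs)
  spacing <- tree$spacing
  branches <- tree$branches
  junctions <- tree$junctions

  do_host <- function(label, junction_name) {
    sp <- specs[[label]]
    if (is.null(sp)) stopf("missing vessel spec '%s'", label)
    j <- junctions[[junction_name]]
    b <- branches[[label]]
    s_j <- j$host_s
    total <- max(b$arc)
    # Side targets in flow order: length before the junction, after it.
    if (label == "artery") {
      before <- sp$proximal_multiple * sp$diameter   # proximal artery
      after  <- sp$distal_multiple * sp$diameter     # distal artery
    } else {
      before <- sp$distal_multiple * sp$diameter     # distal vein
      after  <- sp$proximal_multiple * sp$diameter   # proximal vein
    }
    if (before + after <= 0)
      stopf("branch '%s' reduced to its anastomosis point (zero length)",
            label)
    if (s_j < before - 1e-6)
      stopf("branch '%s' shorter than requested trim length on the %s side",
            label, "upstream")
    if (total - s_j < after - 1e-6)
      stopf("branch '%s' shorter than requested trim length on the %s side",
            label, "downstream")
    side_before <- if (before > 0)
      extend_side(slice_branch(b, s_j, s_j - before), before, spacing)
    else matrix(j$point, 1, 3)
    side_after <- if (after > 0)
      extend_side(slice_branch(b, s_j, s_j + after), after, spacing)
    else matrix(j$point, 1, 3)
    pts <- rbind(side_before[rev(seq_len(nrow(side_before))), , drop = FALSE],
                 side_after[-1L, , drop = FALSE])
    nb <- make_branch(pts, sp$diameter / 2, spacing)
    list(branch = nb, host_s = 2 * before)
  }

  a <- do_host("artery", "arterial")
  v <- do_host("vein", "venous")
  branches$artery <- a$branch
  branches$vein <- v$branch
  junctions$arterial$host_s <- a$host_s
  junctions$venous$host_s <- v$host_s
  centerline_tree(branches, junctions, spacing)
}

#' Segment lengths of a centerline tree
#'
#' Arc lengths, in mm, of the five flow segments delimited by the two
#' anastomoses: proximal/distal artery, graft, distal/proximal vein.
#'
#' @param tree an [centerline_tree()].
#' @return named numeric vector, mm.
#' @export
segment_lengths <- function(tree) {
  ja <- tree$junctions$arterial; jv <- tree$junctions$venous
  c(proximal_artery = ja$host_s,
    distal_artery = max(tree$branches$artery$arc) - ja$host_s,
    graft = max(tree$branches$graft$arc),
    distal_vein = jv$host_s,
    proximal_vein = max(tree$branches$vein$arc) - jv$host_s)
}
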