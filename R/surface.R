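#' Triangulated lumen surfaces
#'
#' A surface geometry is a labelled triangle mesh of the lumen wall:
#' vertices in mm, triangular faces, a label per face (`wall`,
#' `cap:<boundary>` or `junction:<anastomosis>`) and per-face areas in
#' mm^2. Each swept branch is a closed manifold (every edge shared by
#' exactly two faces); per-vertex branch provenance and centerline
#' arc-length coordinates are retained so surface points can be mapped
#' back to the centerline (used by region masks).
#'
#' @param vertices nv x 3 matrix, mm.
#' @param faces nf x 3 integer matrix (1-based vertex indices).
#' @param face_labels character vector, length nf.
#' @param vertex_branch character vector, length nv.
#' @param vertex_s numeric vector, length nv: arc-length coordinate of the
#'   generating centerline point, mm.
#' @return object of class `avg_surface_geometry` (face areas computed).
#' @export
surface_geometry <- function(vertices, faces, face_labels,
                             vertex_branch = NULL, vertex_s = NULL) {
  faces <- matrix(as.integer(faces), ncol = 3)
  areas <- triangle_areas(vertices, faces)
  if (any(areas <= 0)) stopf("surface has degenerate (zero-area) faces")
  structure(list(vertices = vertices, faces = faces,
                 face_labels = face_labels, face_areas = areas,
                 vertex_branch = vertex_branch, vertex_s = vertex_s),
            class = "avg_surface_geometry")
}

triangle_areas <- function(v, f) {
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.avg_surface_geometry <- function(x, ...) {
  cat(sprintf("<avg_surface_geometry> %d vertices, %d faces, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), sum(x$face_areas)))
  tab <- table(x$face_labels)
  for (nm in names(tab)) cat(sprintf("  %-22s %6d faces\n", nm, tab[[nm]]))
  invisible(x)
}

#' Closed-manifold check
#'
#' Verifies that every undirected edge of the mesh is shared by exactly
#' two faces (watertight, no borders, no non-manifold fins).
#'
#' @param surf an `avg_surface_geometry`.
#' @return `TRUE` or `FALSE`.
#' @export
is_closed_manifold <- function(surf) {
  f <- surf$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# Parallel-transport orthonormal frames along a polyline: returns list of
# unit normals n1, n2 per point (minimal-twist).
transport_frames <- function(pts) {
  n <- nrow(pts)
  tangents <- matrix(0, n, 3)
  tangents[1, ] <- unit_vec(pts[2, ] - pts[1, ])
  tangents[n, ] <- unit_vec(pts[n, ] - pts[n - 1, ])
  if (n > 2)
    for (i in 2:(n - 1))
      tangents[i, ] <- unit_vec(pts[i + 1, ] - pts[i - 1, ])
  n1 <- matrix(0, n, 3); n2 <- matrix(0, n, 3)
  ref <- if (abs(tangents[1, 3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  n1[1, ] <- unit_vec(pracma_cross(tangents[1, ], ref))
  n2[1, ] <- pracma_cross(tangents[1, ], n1[1, ])
  for (i in seq_len(n - 1)) {
    # rotate previous normal into the new tangent plane
    v <- n1[i, ] - sum(n1[i, ] * tangents[i + 1, ]) * tangents[i + 1, ]
    n1[i + 1, ] <- unit_vec(v)
    n2[i + 1, ] <- pracma_cross(tangents[i + 1, ], n1[i + 1, ])
  }
  list(t = tangents, n1 = n1, n2 = n2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Minimum radius of curvature of a polyline (circumradius of point
# triples), mm; Inf for straight lines.
min_curvature_radius <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(Inf)
  r <- Inf
  for (i in 2:(n - 1)) {
    a <- vec_norm(pts[i, ] - pts[i - 1, ])
    b <- vec_norm(pts[i + 1, ] - pts[i, ])
    cc <- vec_norm(pts[i + 1, ] - pts[i - 1, ])
    ar <- triangle_areas(rbind(pts[i - 1, ], pts[i, ], pts[i + 1, ]),
                         matrix(1:3, 1))
    if (ar > 1e-12) r <- min(r, a * b * cc / (4 * ar))
  }
  r
}

#' Sweep circular cross-sections along centerlines
#'
#' Imposes constant-radius circular cross-sections onto each branch
#' centerline to build the lumen surface: one closed tube mesh per branch
#' (minimal-twist frames, quad strips split into triangles, planar
#' end-caps as triangle fans). Host-vessel end caps are labelled
#' `cap:arterial_inlet`, `cap:arterial_outlet`, `cap:venous_inlet`,
#' `cap:venous_outlet` in flow order; graft end faces are labelled
#' `junction:arterial` / `junction:venous` and mark the interfaces where
#' the branch tubes meet at the shared anastomosis references (the tubes
#' are emitted as separate closed manifolds rather than a boolean union).
#'
#' @param tree an [centerline_tree()].
#' @param specs vessel specs (radii are taken from the tree itself; specs
#'   are accepted for interface symmetry and validated against the tree).
#' @param ring_spacing axial distance between cross-section rings, mm.
#' @param n_theta vertices per ring.
#' @return an [surface_geometry()].
#' @export
sweep_and_join <- function(tree, specs = NULL, ring_spacing = 1.0,
                           n_theta = 32L) {
  cap_names <- list(
    artery = c("cap:arterial_inlet", "cap:arterial_outlet"),
    vein = c("cap:venous_inlet", "cap:venous_outlet"),
    graft = c("junction:arterial", "junction:venous"))
  verts <- list(); faces <- list(); labels <- list()
  vbranch <- list(); vs <- list(); offset <- 0L

  for (nm in names(tree$branches)) {
    b <- tree$branches[[nm]]
    r <- b$radius[1]
    rs <- resample_polyline(b$points, ring_spacing)
    pts <- rs$points; arc <- rs$arc
    if (min_curvature_radius(pts) < r)
      stopf("self-intersecting sweep: branch '%s' curvature radius < tube radius",
            nm)
    fr <- transport_frames(pts)
    nr <- nrow(pts)
    th <- seq(0, 2 * pi, length.out = n_theta + 1L)[seq_len(n_theta)]
    ring <- function(i)
      matrix(pts[i, ], n_theta, 3, byrow = TRUE) +
        r * (outer(cos(th), fr$n1[i, ]) + outer(sin(th), fr$n2[i, ]))
    v <- do.call(rbind, lapply(seq_len(nr), ring))
    # two cap centers appended at the end
    v <- rbind(v, pts[1, ], pts[nr, ])
    idx <- function(i, k) offset + (i - 1L) * n_theta + ((k - 1L) %% n_theta) + 1L
    f <- vector("list", nr - 1L)
    for (i in seq_len(nr - 1L)) {
      k <- seq_len(n_theta)
      f[[i]] <- rbind(cbind(idx(i, k), idx(i + 1L, k), idx(i + 1L, k + 1L)),
                      cbind(idx(i, k), idx(i + 1L, k + 1L), idx(i, k + 1L)))
    }
    wall_f <- do.call(rbind, f)
    c0 <- offset + nr * n_theta + 1L
    c1 <- c0 + 1L
    k <- seq_len(n_theta)
    cap_start <- cbind(rep(c0, n_theta), idx(1L, k + 1L), idx(1L, k))
    cap_end <- cbind(rep(c1, n_theta), idx(nr, k), idx(nr, k + 1L))
    verts[[nm]] <- v
    faces[[nm]] <- rbind(wall_f, cap_start, cap_end)
    labels[[nm]] <- c(rep("wall", nrow(wall_f)),
                      rep(cap_names[[nm]][1], n_theta),
                      rep(cap_names[[nm]][2], n_theta))
    vbranch[[nm]] <- rep(nm, nrow(v))
    vs[[nm]] <- c(rep(arc, each = n_theta), arc[1], arc[nr])
    offset <- offset + nrow(v)
  }
  surface_geometry(do.call(rbind, verts), do.call(rbind, faces),
                   unlist(labels, use.names = FALSE),
                   unlist(vbranch, use.names = FALSE),
                   unlist(vs, use.names = FALSE))
}

#' Read / write surfaces (ASCII STL and VTK polydata)
#'
#' STL carries geometry only (labels are not representable); the VTK
#' writer adds face labels as integer `CELL_DATA` with the label table in
#' the dataset title. STL reading merges coincident vertices.
#'
#' @param surf an `avg_surface_geometry`.
#' @param path file path.
#' @return `read_surface_stl` returns an `avg_surface_geometry` (labels
#'   all `wall`); writers return `path` invisibly.
#' @export
write_surface_stl <- function(surf, path) {
  v <- surf$vertices; f <- surf$faces
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid avghemo", con)
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nn <- sqrt(rowSums(nrm^2)); nrm <- nrm / pmax(nn, 1e-300)
  out <- character(nrow(f) * 7L)
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    out[(i - 1L) * 7L + 1:7] <- c(
      sprintf("facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
      "  outer loop",
      sprintf("    vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
      "  endloop", "endfacet")
  }
  writeLines(out, con)
  writeLines("endsolid avghemo", con)
  invisible(path)
}

#' @rdname write_surface_stl
#' @export
read_surface_stl <- function(path) {
  ln <- readLines(path)
  vl <- grep("^\\s*vertex", ln, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stopf("malformed STL '%s': vertex count %d not a multiple of 3",
          path, length(vl))
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(tok)
    as.numeric(tok[2:4])))
  key <- apply(round(nums, 9), 1L, paste, collapse = ",")
  uk <- !duplicated(key)
  vid <- match(key, key[uk])             # index into the unique vertex list
  verts <- nums[uk, , drop = FALSE]
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  surface_geometry(verts, faces, rep("wall", nrow(faces)))
}

#' @rdname write_surface_stl
#' @export
write_surface_vtk <- function(surf, path) {
  con <- file(path, "w"); on.exit(close(con))
  labs <- sort(unique(surf$face_labels))
  writeLines(c("# vtk DataFile Version 3.0",
               paste0("avghemo surface labels: ", paste(labs, collapse = ",")),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(surf$vertices))), con)
  writeLines(apply(surf$vertices, 1L, function(p)
    sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
  nf <- nrow(surf$faces)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(apply(surf$faces, 1L, function(fc)
    paste(c(3L, fc - 1L), collapse = " ")), con)
  writeLines(c(sprintf("CELL_DATA %d", nf),
               "SCALARS face_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(surf$face_labels, labs) - 1L), con)
  invisible(path)
}
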