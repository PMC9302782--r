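#' Read and write centerline polylines
#'
#' Two plain-text dialects are supported and round-trip all fields:
#' \describe{
#'   \item{CSV}{columns `branch` (integer id), `label`, `x (mm)`, `y (mm)`,
#'     `z (mm)`, `r (mm)`.}
#'   \item{VTK legacy polydata}{ASCII, `POINTS` + `LINES` + per-point
#'     `SCALARS radius`, one polyline cell per branch; branch labels are
#'     carried in the dataset title line.}
#' }
#'
#' @param tree an [centerline_tree()].
#' @param path file path; format chosen by extension (`.csv` or `.vtk`)
#'   unless `format` is given.
#' @param format `"csv"` or `"vtk"`.
#' @return `write_centerlines` returns `path` invisibly.
#' @export
write_centerlines <- function(tree, path, format = c("auto", "csv", "vtk")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vtk$", path, ignore.case = TRUE)) "vtk" else "csv"
  labs <- names(tree$branches)
  if (format == "csv") {
    rows <- lapply(seq_along(labs), function(i) {
      b <- tree$branches[[labs[i]]]
      data.frame(branch = i, label = labs[i],
                 `x (mm)` = b$points[, 1], `y (mm)` = b$points[, 2],
                 `z (mm)` = b$points[, 3], `r (mm)` = b$radius,
                 check.names = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    npts <- vapply(tree$branches, function(b) nrow(b$points), integer(1))
    writeLines(c("# vtk DataFile Version 3.0",
                 paste0("avghemo centerlines: ", paste(labs, collapse = ",")),
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d float", sum(npts))), con)
    for (b in tree$branches)
      writeLines(apply(b$points, 1L, function(p)
        sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
    writeLines(sprintf("LINES %d %d", length(labs),
                       length(labs) + sum(npts)), con)
    off <- 0L
    for (n in npts) {
      writeLines(paste(c(n, seq.int(off, off + n - 1L)), collapse = " "), con)
      off <- off + n
    }
    writeLines(c(sprintf("POINT_DATA %d", sum(npts)),
                 "SCALARS radius float 1", "LOOKUP_TABLE default"), con)
    for (b in tree$branches)
      writeLines(sprintf("%.9g", b$radius), con)
  }
  invisible(path)
}

read_centerline_polylines <- function(path, format = c("auto", "csv", "vtk")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vtk$", path, ignore.case = TRUE)) "vtk" else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    need <- c("branch", "label")
    if (!all(need %in% names(df)))
      stopf("centerline CSV '%s' lacks columns %s", path,
            paste(setdiff(need, names(df)), collapse = ", "))
    num <- df[, !(names(df) %in% need), drop = FALSE]
    if (ncol(num) < 4L)
      stopf("centerline CSV '%s' needs x, y, z, r columns", path)
    split_idx <- split(seq_len(nrow(df)), df$branch)
    out <- lapply(split_idx, function(ix)
      list(label = as.character(df$label[ix[1]]),
           points = as.matrix(num[ix, 1:3, drop = FALSE]),
           radius = num[ix, 4]))
    stats::setNames(out, vapply(out, `[[`, character(1), "label"))
  } else {
    ln <- readLines(path)
    title <- ln[2]
    labs <- NULL
    if (grepl("centerlines:", title))
      labs <- trimws(strsplit(sub(".*centerlines:", "", title), ",")[[1]])
    ip <- grep("^POINTS", ln)[1]
    np <- as.integer(strsplit(trimws(ln[ip]), "\\s+")[[1]][2])
    pts_tok <- scan(text = paste(ln[(ip + 1):length(ln)], collapse = "\n"),
                    what = numeric(), n = 3L * np, quiet = TRUE)
    pts <- matrix(pts_tok, ncol = 3, byrow = TRUE)
    il <- grep("^LINES", ln)[1]
    nl <- as.integer(strsplit(trimws(ln[il]), "\\s+")[[1]][2])
    conn <- lapply(seq_len(nl), function(k) {
      v <- as.integer(strsplit(trimws(ln[il + k]), "\\s+")[[1]])
      v[-1L] + 1L
    })
    ir <- grep("^SCALARS radius", ln)[1]
    radius <- if (!is.na(ir))
      scan(text = paste(ln[(ir + 2):length(ln)], collapse = "\n"),
           what = numeric(), n = np, quiet = TRUE)
    else rep(1, np)
    if (is.null(labs) || length(labs) != nl)
      labs <- paste0("branch_", seq_len(nl))
    out <- lapply(seq_len(nl), function(k)
      list(label = labs[k], points = pts[conn[[k]], , drop = FALSE],
           radius = radius[conn[[k]]]))
    stats::setNames(out, labs)
  }
}

#' Import centerlines and locate anastomoses
#'
#' Reads labelled branch polylines (CSV or VTK legacy polydata), collapses
#' duplicate consecutive points, resamples every branch to uniform
#' arc-length spacing, and locates the two anastomosis references as the
#' closest-approach points between the graft and each host polyline (ties
#' broken towards smaller host arc length by the scan order). The graft is
#' reordered, if necessary, to run from the arterial to the venous
#' junction.
#'
#' @param path polyline file.
#' @param labels optional relabelling: named character vector mapping file
#'   labels to `artery`, `vein`, `graft`.
#' @param spacing resampling spacing, mm.
#' @param format `"auto"`, `"csv"` or `"vtk"`.
#' @return an [centerline_tree()].
#' @export
import_centerlines <- function(path, labels = NULL, spacing = 0.25,
                               format = c("auto", "csv", "vtk")) {
  polys <- read_centerline_polylines(path, match.arg(format))
  if (!is.null(labels))
    names(polys) <- unname(labels[names(polys)])
  for (nm in c("artery", "vein", "graft"))
    if (!nm %in% names(polys)) stopf("missing branch label '%s'", nm)
  branches <- lapply(polys[c("artery", "vein", "graft")], function(p) {
    pts <- collapse_duplicates(p$points)
    if (nrow(pts) < 2L) stopf("degenerate (zero-length) polyline '%s'",
                              p$label)
    rs <- resample_polyline(pts, spacing)
    r <- mean(p$radius)
    list(points = rs$points, arc = rs$arc, radius = rep(r, nrow(rs$points)))
  })

  locate <- function(host) {
    ca <- closest_approach(branches$graft$points, branches[[host]]$points)
    list(point = (branches$graft$points[ca$i, ] +
                    branches[[host]]$points[ca$j, ]) / 2,
         host = host,
         host_s = branches[[host]]$arc[ca$j],
         graft_s = branches$graft$arc[ca$i])
  }
  ja <- locate("artery"); jv <- locate("vein")
  if (ja$graft_s > jv$graft_s) {         # graft runs venous -> arterial
    g <- branches$graft
    g$points <- g$points[rev(seq_len(nrow(g$points))), , drop = FALSE]
    total <- max(g$arc)
    g$arc <- rev(total - g$arc)
    branches$graft <- g
    ja$graft_s <- total - ja$graft_s
    jv$graft_s <- total - jv$graft_s
  }
  centerline_tree(branches, list(arterial = ja, venous = jv), spacing)
}
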