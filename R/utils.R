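# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("'%s' must be a single positive finite number", name)
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stopf("'%s' must be a single non-negative finite number", name)
  invisible(x)
}

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stopf("cannot normalise a zero vector")
  v / n
}

# Angle between two 3D vectors, degrees, in [0, 180].
angle_between <- function(a, b) {
  ca <- sum(unit_vec(a) * unit_vec(b))
  ca <- max(-1, min(1, ca))
  acos(ca) * 180 / pi
}

# Cumulative arc length of an n x 3 polyline.
arc_length <- function(pts) {
  if (nrow(pts) < 2L) return(rep(0, nrow(pts)))
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# Drop consecutive duplicate points (within tol) from an n x 3 polyline.
collapse_duplicates <- function(pts, tol = 1e-9) {
  if (nrow(pts) < 2L) return(pts)
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  keep <- c(TRUE, d > tol)
  pts[keep, , drop = FALSE]
}

# Resample an n x 3 polyline to uniform arc-length spacing (linear
# interpolation between input points); spacing in the same unit as pts.
resample_polyline <- function(pts, spacing) {
  pts <- collapse_duplicates(pts)
  s <- arc_length(pts)
  total <- s[length(s)]
  if (total <= 0) stopf("degenerate (zero-length) polyline")
  n_out <- max(2L, ceiling(total / spacing) + 1L)
  s_new <- seq(0, total, length.out = n_out)
  out <- vapply(1:3, function(k) stats::approx(s, pts[, k], xout = s_new)$y,
                numeric(n_out))
  list(points = out, arc = s_new)
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Closest pair of points between two polylines; returns indices and distance.
closest_approach <- function(a, b) {
  # O(n*m) scan; centerlines are a few hundred points after resampling at
  # test scale, so this stays cheap.
  best <- list(i = 1L, j = 1L, dist = Inf)
  for (i in seq_len(nrow(a))) {
    d2 <- rowSums((b - matrix(a[i, ], nrow(b), 3, byrow = TRUE))^2)
    j <- which.min(d2)
    if (d2[j] < best$dist^2) best <- list(i = i, j = j, dist = sqrt(d2[j]))
  }
  best
}
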