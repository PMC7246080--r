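# Planar polygon primitives shared by the anatomy simulator, the feature
# extractor and the overlap/registration code.
#
# A contour is an n x 2 numeric matrix with columns `a` (anterior-posterior,
# anterior-positive) and `s` (superior-inferior, superior-positive), in mm.
# Vertices are ordered counter-clockwise and the polygon is implicitly closed
# (last vertex joins the first).

#' Build a closed planar contour
#'
#' Validates and normalizes a simple closed polygon given as vertex
#' coordinates. The vertex order is normalized to counter-clockwise.
#'
#' @param a,s Numeric vectors of equal length (>= 3): AP (anterior-positive)
#'   and SI (superior-positive) vertex coordinates in mm.
#' @param check_simple Verify that the boundary does not self-intersect.
#' @return An n x 2 matrix with columns `a`, `s` and class `ctv_contour`.
#' @export
contour <- function(a, s, check_simple = TRUE) {
  if (length(a) != length(s)) stop("`a` and `s` must have equal length")
  if (length(a) < 3L) stop("a contour needs at least 3 vertices")
  if (!all(is.finite(a)) || !all(is.finite(s))) {
    stop("contour coordinates must be finite")
  }
  m <- cbind(a = as.numeric(a), s = as.numeric(s))
  ar <- signed_area(m)
  if (abs(ar) < 1e-12) stop("contour has (near-)zero enclosed area")
  if (ar < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (check_simple && !is_simple_polygon(m)) {
    stop("contour boundary is self-intersecting")
  }
  class(m) <- c("ctv_contour", class(m))
  m
}

as_contour <- function(m, check_simple = FALSE) {
  contour(m[, 1L], m[, 2L], check_simple = check_simple)
}

signed_area <- function(p) {
  a <- p[, 1L]; s <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  sum(a * s[j] - a[j] * s) / 2
}

#' Polygon area (shoelace formula)
#' @param p A contour (n x 2 matrix).
#' @return Enclosed area in mm^2 (positive).
#' @export
polygon_area <- function(p) abs(signed_area(p))

#' Polygon centroid
#' @param p A contour (n x 2 matrix).
#' @return Length-2 vector `c(a, s)`.
#' @export
polygon_centroid <- function(p) {
  a <- p[, 1L]; s <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  cr <- a * s[j] - a[j] * s
  ar <- sum(cr) / 2
  c(a = sum((a + a[j]) * cr) / (6 * ar), s = sum((s + s[j]) * cr) / (6 * ar))
}

# Segment-pair intersection test over all non-adjacent edge pairs, vectorized
# over pairs. O(V^2) but V is ~48-64 for generated organs.
is_simple_polygon <- function(p) {
  n <- nrow(p)
  j <- c(seq_len(n)[-1L], 1L)
  p1 <- p; p2 <- p[j, , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, k) {
    k > i + 1L & !(i == 1L & k == n)
  }), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(TRUE)
  i <- idx[, 1L]; k <- idx[, 2L]
  d1 <- p2[i, ] - p1[i, ]
  d2 <- p2[k, ] - p1[k, ]
  w <- p1[k, ] - p1[i, ]
  den <- d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]
  t1 <- (w[, 1L] * d2[, 2L] - w[, 2L] * d2[, 1L]) / den
  t2 <- (w[, 1L] * d1[, 2L] - w[, 2L] * d1[, 1L]) / den
  cross <- is.finite(t1) & is.finite(t2) &
    t1 > 1e-12 & t1 < 1 - 1e-12 & t2 > 1e-12 & t2 < 1 - 1e-12
  !any(cross)
}

#' Test points for polygon inclusion
#'
#' Even-odd ray-casting, vectorized over points. Points exactly on the
#' boundary may fall on either side (measure-zero set for the synthetic
#' anatomies used here).
#'
#' @param pts m x 2 matrix of `(a, s)` points.
#' @param poly A contour.
#' @return Logical vector of length m.
#' @export
point_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  x <- pts[, 1L]; y <- pts[, 2L]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    xi <- poly[k, 1L]; yi <- poly[k, 2L]
    xj <- poly[j[k], 1L]; yj <- poly[j[k], 2L]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Intersections of an axis-parallel line with a polygon boundary
#'
#' @param poly A contour.
#' @param axis `"s"` for the horizontal line `s = level` (returns the `a`
#'   coordinates of the crossings), `"a"` for the vertical line `a = level`
#'   (returns the `s` coordinates).
#' @param level Line position in mm.
#' @return Sorted numeric vector of crossing coordinates (possibly empty).
#' @export
line_polygon_intersections <- function(poly, axis = c("s", "a"), level) {
  axis <- match.arg(axis)
  fix <- if (axis == "s") poly[, 2L] else poly[, 1L]
  var <- if (axis == "s") poly[, 1L] else poly[, 2L]
  n <- length(fix)
  j <- c(seq_len(n)[-1L], 1L)
  f1 <- fix; f2 <- fix[j]; v1 <- var; v2 <- var[j]
  # half-open rule: an edge contributes iff it strictly straddles the level,
  # counting a vertex on the line with its 'upper' edge only
  cross <- (f1 <= level & f2 > level) | (f2 <= level & f1 > level)
  t <- (level - f1[cross]) / (f2[cross] - f1[cross])
  sort(v1[cross] + t * (v2[cross] - v1[cross]))
}

#' Translate a contour
#' @param poly A contour.
#' @param da,ds Translation along AP and SI, mm.
#' @export
translate_contour <- function(poly, da, ds) {
  out <- poly
  out[, 1L] <- poly[, 1L] + da
  out[, 2L] <- poly[, 2L] + ds
  out
}

#' Is a polygon convex?
#' @param poly A contour.
#' @param tol Relative tolerance on cross products.
#' @export
is_convex_polygon <- function(poly, tol = 1e-9) {
  n <- nrow(poly)
  j <- c(seq_len(n)[-1L], 1L)
  k <- c(j[-1L], j[1L])
  e1 <- poly[j, , drop = FALSE] - poly
  e2 <- poly[k, , drop = FALSE] - poly[j, , drop = FALSE]
  cr <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  scale <- max(abs(cr), 1e-300)
  all(cr >= -tol * scale)
}

# Sutherland-Hodgman: clip `subject` by the convex polygon `clip` (CCW).
clip_by_convex <- function(subject, clip) {
  n <- nrow(clip)
  out <- subject
  for (k in seq_len(n)) {
    if (nrow(out) == 0L) return(out)
    p1 <- clip[k, ]
    p2 <- clip[if (k == n) 1L else k + 1L, ]
    ea <- p2[1L] - p1[1L]; es <- p2[2L] - p1[2L]
    side <- ea * (out[, 2L] - p1[2L]) - es * (out[, 1L] - p1[1L])
    m <- nrow(out)
    jj <- c(seq_len(m)[-1L], 1L)
    res <- matrix(numeric(0), ncol = 2L)
    for (i in seq_len(m)) {
      cur <- out[i, ]; nxt <- out[jj[i], ]
      cin <- side[i] >= 0; nin <- side[jj[i]] >= 0
      if (cin) res <- rbind(res, cur)
      if (cin != nin) {
        t <- side[i] / (side[i] - side[jj[i]])
        res <- rbind(res, cur + t * (nxt - cur))
      }
    }
    out <- res
  }
  out
}

#' Area of intersection of two polygons
#'
#' Computed by Sutherland-Hodgman clipping; at least one of the two polygons
#' must be convex (true for all generated organ contours).
#'
#' @param A,B Contours.
#' @return Intersection area in mm^2.
#' @export
polygon_intersection_area <- function(A, B) {
  if (is_convex_polygon(B)) {
    clipped <- clip_by_convex(A, B)
  } else if (is_convex_polygon(A)) {
    clipped <- clip_by_convex(B, A)
  } else {
    stop("polygon_intersection_area() needs at least one convex polygon")
  }
  if (nrow(clipped) < 3L) return(0)
  abs(signed_area(clipped))
}

#' Smooth star-convex organ contour (superellipse)
#'
#' `|x/ra|^m + |y/rs|^m = 1`; `m >= 2` gives a convex outline, larger `m`
#' approaches a rounded rectangle (used for the rectal tube).
#'
#' @param center Length-2 `(a, s)` center, mm.
#' @param ra,rs Semi-axes along AP and SI, mm.
#' @param m Superellipse exponent (>= 2 for convexity).
#' @param n Number of vertices (>= 48 recommended).
#' @export
superellipse_contour <- function(center, ra, rs, m = 2, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ct <- cos(th); st <- sin(th)
  a <- center[1L] + ra * sign(ct) * abs(ct)^(2 / m)
  s <- center[2L] + rs * sign(st) * abs(st)^(2 / m)
  contour(a, s, check_simple = FALSE)
}

#' Expand a contour radially outward
#'
#' Moves every vertex away from the centroid by `margin` mm; used to form
#' the registration region of interest (CTV plus margin).
#'
#' @param poly A contour.
#' @param margin Outward margin in mm.
#' @export
expand_contour <- function(poly, margin) {
  cen <- polygon_centroid(poly)
  d <- sweep(unclass(poly), 2L, cen)
  r <- sqrt(rowSums(d^2))
  out <- poly
  out[, 1L] <- cen[1L] + d[, 1L] * (r + margin) / r
  out[, 2L] <- cen[2L] + d[, 2L] * (r + margin) / r
  out
}
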