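# Small planar-geometry primitives used throughout the package. All coordinates
# are projected meters; polygons are 2-column matrices of vertices (not closed).

#' Polygon area by the shoelace formula
#'
#' @param poly Two-column matrix of vertex coordinates (meters), unclosed.
#' @return Area in square meters (always non-negative).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Clip a convex polygon to an axis-aligned rectangle
#'
#' Sutherland--Hodgman clipping against each of the four half-planes in turn.
#' Used to compute population-polygon / grid-cell intersection areas.
#'
#' @param poly Two-column vertex matrix (convex).
#' @param xmin,xmax,ymin,ymax Rectangle bounds.
#' @return Clipped vertex matrix (possibly 0 rows).
#' @export
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip_half <- function(p, inside, intersect) {
    if (nrow(p) == 0L) return(p)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(p)
    for (i in seq_len(n)) {
      a <- p[i, ]; b <- p[if (i == n) 1L else i + 1L, ]
      ain <- inside(a); bin <- inside(b)
      if (ain) out <- rbind(out, a)
      if (xor(ain, bin)) out <- rbind(out, intersect(a, b))
    }
    out
  }
  ix <- function(a, b, v, k) {
    # intersection of segment a-b with coordinate-k = v
    t <- (v - a[k]) / (b[k] - a[k])
    a + t * (b - a)
  }
  p <- poly
  p <- clip_half(p, function(q) q[1] >= xmin, function(a, b) ix(a, b, xmin, 1))
  p <- clip_half(p, function(q) q[1] <= xmax, function(a, b) ix(a, b, xmax, 1))
  p <- clip_half(p, function(q) q[2] >= ymin, function(a, b) ix(a, b, ymin, 2))
  p <- clip_half(p, function(q) q[2] <= ymax, function(a, b) ix(a, b, ymax, 2))
  p
}

#' Minimum distance from points to a set of line segments or points
#'
#' @param pts Two-column matrix of query points.
#' @param features Either a two-column matrix of points, or a list of segments,
#'   each a 2x2 matrix (rows = endpoints).
#' @return Numeric vector of Euclidean distances (meters).
#' @export
min_feature_distance <- function(pts, features) {
  pts <- rbind(pts)
  if (is.matrix(features)) {
    d2 <- outer(pts[, 1], features[, 1], "-")^2 + outer(pts[, 2], features[, 2], "-")^2
    return(sqrt(apply(d2, 1, min)))
  }
  stopifnot(is.list(features), length(features) >= 1L)
  d <- rep(Inf, nrow(pts))
  for (seg in features) {
    a <- seg[1, ]; b <- seg[2, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      ds <- sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
      ds <- sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
    }
    d <- pmin(d, ds)
  }
  d
}

#' Test whether points lie inside a rectangle boundary
#' @keywords internal
in_rect <- function(pts, xmin, xmax, ymin, ymax) {
  pts[, 1] >= xmin & pts[, 1] <= xmax & pts[, 2] >= ymin & pts[, 2] <= ymax
}
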