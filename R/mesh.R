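#' Build a triangulation mesh over a domain boundary
#'
#' Nodes are placed on a regular lattice covering the boundary's bounding box
#' plus an extension ring, and each lattice square is split into two right
#' triangles (a Delaunay triangulation of the lattice). The node spacing is the
#' largest value compatible with the interior maximum edge length (diagonal
#' edges have length spacing * sqrt(2)), and must respect the minimum-distance
#' cutoff. The extension ring damps the boundary effect of the SPDE
#' approximation; no predictions are made there.
#'
#' @param boundary Vertex matrix of the (rectangular) domain boundary, or a
#'   \code{fern_domain}.
#' @param max_edge_inner Maximum triangle edge length inside the domain (m).
#' @param max_edge_outer Maximum edge length in the extension ring (m).
#' @param extension Width of the extension beyond the boundary (m).
#' @param cutoff Minimum allowed distance between mesh nodes (m).
#' @return Object of class \code{fern_mesh}: \code{loc} (node coordinates),
#'   \code{tv} (triangle-vertex index matrix), \code{interior} (logical per
#'   node), \code{spacing}.
#' @export
build_mesh <- function(boundary, max_edge_inner = 1000, max_edge_outer = 2000,
                       extension = 2000, cutoff = 200) {
  if (inherits(boundary, "fern_domain")) boundary <- boundary$boundary
  if (!is.matrix(boundary) || nrow(boundary) < 3L || any(!is.finite(boundary)))
    stop("boundary must be a finite vertex matrix with at least 3 vertices")
  if (max_edge_inner <= 0 || extension < 0 || cutoff < 0)
    stop("mesh parameters must be positive")
  spacing <- max_edge_inner / sqrt(2)
  if (spacing < cutoff)
    stop("cutoff incompatible with max_edge_inner: nodes closer than cutoff required")
  xr <- range(boundary[, 1]); yr <- range(boundary[, 2])
  gx <- seq(xr[1] - extension, xr[2] + extension,
            length.out = max(2L, ceiling(diff(xr) / spacing + 2 * extension / spacing) + 1L))
  gy <- seq(yr[1] - extension, yr[2] + extension,
            length.out = max(2L, ceiling(diff(yr) / spacing + 2 * extension / spacing) + 1L))
  nxg <- length(gx); nyg <- length(gy)
  loc <- cbind(rep(gx, times = nyg), rep(gy, each = nxg))
  # two triangles per lattice square, consistent diagonal orientation
  tv <- matrix(0L, nrow = 2L * (nxg - 1L) * (nyg - 1L), ncol = 3L)
  k <- 0L
  for (j in seq_len(nyg - 1L)) {
    base <- (j - 1L) * nxg
    for (i in seq_len(nxg - 1L)) {
      v00 <- base + i; v10 <- v00 + 1L
      v01 <- v00 + nxg; v11 <- v01 + 1L
      tv[k + 1L, ] <- c(v00, v10, v11)
      tv[k + 2L, ] <- c(v00, v11, v01)
      k <- k + 2L
    }
  }
  tol <- 1e-9 * max(diff(xr), diff(yr))
  interior <- loc[, 1] >= xr[1] - tol & loc[, 1] <= xr[2] + tol &
    loc[, 2] >= yr[1] - tol & loc[, 2] <= yr[2] + tol
  structure(list(loc = loc, tv = tv, interior = interior, spacing = diff(gx[1:2]),
                 bbox = c(xr[1] - extension, xr[2] + extension,
                          yr[1] - extension, yr[2] + extension)),
            class = "fern_mesh")
}

#' @export
print.fern_mesh <- function(x, ...) {
  cat(sprintf("fern_mesh: %d nodes, %d triangles, spacing %.1f m\n",
              nrow(x$loc), nrow(x$tv), x$spacing))
  invisible(x)
}

#' Sparse barycentric projector from mesh nodes to point locations
#'
#' Each row carries the barycentric weights of the triangle containing the
#' location, so projecting a nodal field evaluates its piecewise-linear
#' interpolant; weights in every row sum to one.
#'
#' @param mesh A \code{fern_mesh}.
#' @param locations Two-column coordinate matrix.
#' @return Sparse \code{dgCMatrix}, \code{nrow(locations)} x \code{n_nodes}.
#' @export
projector <- function(mesh, locations) {
  locations <- rbind(locations)
  n <- nrow(locations)
  ii <- jj <- xx <- vector("list", n)
  assigned <- rep(FALSE, n)
  loc <- mesh$loc; tv <- mesh$tv
  tol <- 1e-9 * max(abs(mesh$bbox))
  for (t in seq_len(nrow(tv))) {
    todo <- which(!assigned)
    if (!length(todo)) break
    a <- loc[tv[t, 1], ]; b <- loc[tv[t, 2], ]; c <- loc[tv[t, 3], ]
    det <- (b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])
    px <- locations[todo, 1] - a[1]; py <- locations[todo, 2] - a[2]
    l2 <- (px * (c[2] - a[2]) - py * (c[1] - a[1])) / det
    l3 <- (py * (b[1] - a[1]) - px * (b[2] - a[2])) / det
    l1 <- 1 - l2 - l3
    inside <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    hit <- todo[inside]
    if (length(hit)) {
      w <- cbind(l1[inside], l2[inside], l3[inside])
      w <- pmax(w, 0); w <- w / rowSums(w)
      for (q in seq_along(hit)) {
        ii[[hit[q]]] <- rep(hit[q], 3L)
        jj[[hit[q]]] <- tv[t, ]
        xx[[hit[q]]] <- w[q, ]
      }
      assigned[hit] <- TRUE
    }
  }
  if (any(!assigned))
    stop("locations outside mesh: ", paste(which(!assigned), collapse = ", "))
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, nrow(loc)))
}
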