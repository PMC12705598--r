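#' Generate a regular analysis grid over a square study domain
#'
#' Builds the prediction grid used everywhere downstream: a square boundary of
#' side \code{extent_m} tiled by \code{cell_size_m} x \code{cell_size_m} cells,
#' with cell ids assigned row-major from the south-west corner, and an integer
#' year axis. The construction is fully deterministic; \code{seed} is accepted
#' for interface uniformity with the other generators.
#'
#' @param seed Integer seed (kept for a uniform generator interface).
#' @param extent_m Side length of the square domain in meters; must be a
#'   positive multiple of \code{cell_size_m}.
#' @param cell_size_m Cell side length in meters (> 0).
#' @param n_years Number of annual time points (>= 2).
#' @param year_start First calendar year of the series.
#' @return An object of class \code{fern_domain}: list with \code{boundary}
#'   (vertex matrix), \code{cells} (data.frame: cell_id, x, y, area),
#'   \code{cell_size}, \code{extent}, \code{nx}, \code{years}.
#' @examples
#' d <- generate_domain(1, extent_m = 1000, cell_size_m = 100, n_years = 3)
#' nrow(d$cells)  # 100
#' @export
generate_domain <- function(seed = 1L, extent_m = 10000, cell_size_m = 100,
                            n_years = 10L, year_start = 2014L) {
  if (!is.numeric(extent_m) || extent_m <= 0 || !is.numeric(cell_size_m) ||
      cell_size_m <= 0)
    stop("extent_m and cell_size_m must be positive")
  if (abs(extent_m / cell_size_m - round(extent_m / cell_size_m)) > 1e-9)
    stop("extent_m must be divisible by cell_size_m")
  if (n_years < 2) stop("n_years must be at least 2")
  nx <- as.integer(round(extent_m / cell_size_m))
  ctr <- (seq_len(nx) - 0.5) * cell_size_m
  cells <- data.frame(
    cell_id = seq_len(nx * nx),
    x = rep(ctr, times = nx),
    y = rep(ctr, each = nx),
    area = cell_size_m^2
  )
  boundary <- cbind(c(0, extent_m, extent_m, 0), c(0, 0, extent_m, extent_m))
  structure(list(boundary = boundary, cells = cells, cell_size = cell_size_m,
                 extent = extent_m, nx = nx,
                 years = year_start + seq_len(n_years) - 1L),
            class = "fern_domain")
}

#' @export
print.fern_domain <- function(x, ...) {
  cat(sprintf("fern_domain: %d x %d cells of %g m (%g m extent), years %d-%d\n",
              x$nx, x$nx, x$cell_size, x$extent, min(x$years), max(x$years)))
  invisible(x)
}

#' Map point coordinates to grid cell ids
#' @param domain A \code{fern_domain}.
#' @param pts Two-column coordinate matrix.
#' @return Integer vector of cell ids (NA outside the domain).
#' @export
cell_of <- function(domain, pts) {
  pts <- rbind(pts)
  cs <- domain$cell_size
  ix <- floor(pts[, 1] / cs) + 1L
  iy <- floor(pts[, 2] / cs) + 1L
  ix[pts[, 1] == domain$extent] <- domain$nx
  iy[pts[, 2] == domain$extent] <- domain$nx
  ok <- ix >= 1L & ix <= domain$nx & iy >= 1L & iy <= domain$nx
  out <- rep(NA_integer_, nrow(pts))
  out[ok] <- (iy[ok] - 1L) * domain$nx + ix[ok]
  out
}
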