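# Count observations: proportional redistribution of population totals onto
# grid cells, and readers/writers for the on-disk observation schemas.

#' Intersect a population polygon with the analysis grid
#' @keywords internal
population_cell_areas <- function(poly, domain) {
  cs <- domain$cell_size
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  if (xr[1] < 0 || yr[1] < 0 || xr[2] > domain$extent || yr[2] > domain$extent)
    stop("population polygon extends outside the domain")
  ix <- max(1L, floor(xr[1] / cs) + 1L):min(domain$nx, floor((xr[2] - 1e-9) / cs) + 1L)
  iy <- max(1L, floor(yr[1] / cs) + 1L):min(domain$nx, floor((yr[2] - 1e-9) / cs) + 1L)
  out <- data.frame(cell_id = integer(0), area = numeric(0))
  for (j in iy) for (i in ix) {
    p <- clip_polygon_rect(poly, (i - 1L) * cs, i * cs, (j - 1L) * cs, j * cs)
    if (nrow(p) >= 3L) {
      a <- polygon_area(p)
      if (a > 0)
        out <- rbind(out, data.frame(cell_id = (j - 1L) * domain$nx + i, area = a))
    }
  }
  out
}

#' Largest-remainder integer apportionment
#'
#' Distributes an integer \code{total} over shares proportional to
#' \code{weights}, preserving the total exactly and breaking remainder ties by
#' index order (deterministic).
#'
#' @param total Non-negative integer.
#' @param weights Non-negative weights (at least one positive).
#' @return Integer vector summing to \code{total}.
#' @export
largest_remainder <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  q <- total * weights / sum(weights)
  base <- floor(q)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Redistribute population-level counts onto grid cells
#'
#' Assumes individuals are homogeneously distributed within each population
#' polygon: cell shares are proportional to the polygon/cell intersection
#' area, integerized by largest-remainder rounding so the cell counts sum
#' exactly to the recorded population count. The intersection area becomes the
#' observation's sampled-area offset.
#'
#' @param population_counts data.frame: \code{population}, \code{species},
#'   \code{year}, \code{count} (NA = year not surveyed).
#' @param population_polygons Named list (by population id) of vertex matrices.
#' @param domain A \code{fern_domain}.
#' @return data.frame of count observations: species, population, cell_id,
#'   year, count, area_m2, missing.
#' @export
redistribute_counts <- function(population_counts, population_polygons, domain) {
  out <- vector("list", nrow(population_counts))
  cellareas <- lapply(population_polygons, population_cell_areas, domain = domain)
  for (p in names(cellareas))
    if (nrow(cellareas[[p]]) == 0L)
      stop("population ", p, " does not intersect the domain grid")
  for (i in seq_len(nrow(population_counts))) {
    r <- population_counts[i, ]
    ca <- cellareas[[as.character(r$population)]]
    if (is.null(ca)) stop("no polygon for population ", r$population)
    miss <- is.na(r$count)
    cnt <- if (miss) rep(NA_integer_, nrow(ca)) else largest_remainder(r$count, ca$area)
    out[[i]] <- data.frame(species = r$species, population = r$population,
                           cell_id = ca$cell_id, year = r$year, count = cnt,
                           area_m2 = ca$area, missing = miss)
  }
  do.call(rbind, out)
}

#' Read and validate an observation set from disk
#'
#' @param counts_path CSV with columns species, population, cell_id, year,
#'   count, area_m2, missing.
#' @param presences_path CSV with columns species, cell_id, year, present,
#'   log_road_dist (may be empty / missing when no fusion is intended).
#' @param populations_path Optional GeoJSON of population polygons.
#' @return List with \code{counts}, \code{presences}, \code{polygons}.
#' @export
load_observations <- function(counts_path, presences_path = NULL,
                              populations_path = NULL) {
  counts <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
  need <- c("species", "population", "cell_id", "year", "count", "area_m2", "missing")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("counts file missing columns: ", paste(miss, collapse = ", "))
  for (col in c("cell_id", "year")) {
    bad <- which(!is.finite(counts[[col]]))
    if (length(bad)) stop("malformed ", col, " in counts row ", bad[1])
  }
  if (any(counts$area_m2 <= 0)) stop("non-positive offset area in counts")
  if (any(!counts$missing & counts$count < 0, na.rm = TRUE))
    stop("negative counts present")
  if (any(counts$missing & !is.na(counts$count)))
    stop("missing flag set but count present")
  presences <- NULL
  if (!is.null(presences_path) && file.exists(presences_path)) {
    presences <- utils::read.csv(presences_path, stringsAsFactors = FALSE)
    if (nrow(presences)) {
      needp <- c("species", "cell_id", "year", "present")
      missp <- setdiff(needp, names(presences))
      if (length(missp)) stop("presences file missing columns: ",
                              paste(missp, collapse = ", "))
      if (!all(presences$present %in% c(0L, 1L))) stop("presence indicator must be 0/1")
    }
  }
  polygons <- if (!is.null(populations_path) && file.exists(populations_path))
    read_polygons_geojson(populations_path) else NULL
  list(counts = counts, presences = presences, polygons = polygons)
}

#' Write population polygons as GeoJSON
#' @param polygons Named list of vertex matrices.
#' @param meta Optional data.frame with a row per polygon (matched by name).
#' @param path Output path.
#' @export
write_polygons_geojson <- function(polygons, path, meta = NULL) {
  feats <- lapply(names(polygons), function(nm) {
    p <- polygons[[nm]]
    ring <- rbind(p, p[1, , drop = FALSE])
    props <- list(population = nm)
    if (!is.null(meta) && nm %in% meta$population)
      props <- c(props, as.list(meta[meta$population == nm, setdiff(names(meta), "population"), drop = FALSE]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read population polygons from GeoJSON
#' @param path GeoJSON path written by \code{write_polygons_geojson}.
#' @return Named list of vertex matrices.
#' @export
read_polygons_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  out <- list()
  for (f in g$features) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    out[[f$properties$population]] <- m[-nrow(m), , drop = FALSE]
  }
  out
}
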