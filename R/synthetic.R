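# Synthetic-data generator. The monitoring data the models were designed for
# are restricted-access, so every downstream stage is exercised on simulated
# data with the same statistical shape: 3 species, 22/17/11 population
# polygons (0.11-3.81 ha), 10 annual surveys with population-specific missing
# years (median rate ~27%), ~47 road-biased presence locations replicated as
# timeless annual records, and smooth spatially structured covariates.

#' Default covariate field parameters
#'
#' Each climate/terrain covariate is a Matern field on the mesh (sampled with
#' the same SPDE machinery the models use) with a per-year linear trend for
#' climate series; canopy structure is a 4-part composition via a softmax of
#' Gaussian fields. A latent "humidity" field is mixed into several covariates
#' to induce realistic cross-correlations.
#'
#' @return List of per-covariate parameter lists.
#' @export
fern_field_params <- function() {
  list(
    bio01 = list(range = 4000, sigma = 1, trend = -0.03, mix = -0.5),
    bio07 = list(range = 4000, sigma = 1, trend = 0.02, mix = -0.3),
    bio16 = list(range = 5000, sigma = 1, trend = 0.00, mix = 0.6),
    tpi = list(range = 800, sigma = 1, trend = 0, mix = -0.4),
    canopy = list(range = 1200, sigma = 1),
    humidity = list(range = 3000, sigma = 1),
    n_roads = 3L, n_rivers = 2L
  )
}

#' Generate a synthetic covariate stack on a domain
#'
#' @param domain A \code{fern_domain}.
#' @param seed Integer seed.
#' @param field_params See \code{fern_field_params}.
#' @param mesh Optional prebuilt mesh (built at covariate scale otherwise).
#' @return List: \code{table} (long data.frame cell_id, year, name, value),
#'   \code{canopy} (per-cell proportions matrix), \code{roads}, \code{rivers}
#'   (segment lists), \code{mesh}.
#' @export
generate_covariates <- function(domain, seed = 1L, field_params = fern_field_params(),
                                mesh = NULL) {
  for (nm in c("bio01", "bio07", "bio16", "tpi", "canopy", "humidity")) {
    fp <- field_params[[nm]]
    if (!is.null(fp$sigma) && fp$sigma < 0) stop("negative variance for ", nm)
    if (!is.null(fp$range) && fp$range <= 0) stop("non-positive range for ", nm)
  }
  set.seed(seed)
  if (is.null(mesh)) {
    edge <- max(domain$cell_size * 2, domain$extent / 14)
    mesh <- mesh_with_fem(build_mesh(domain, max_edge_inner = edge,
                                     max_edge_outer = 2 * edge,
                                     extension = domain$extent / 5,
                                     cutoff = edge / 10))
  } else mesh <- mesh_with_fem(mesh)
  A <- projector(mesh, as.matrix(domain$cells[, c("x", "y")]))
  draw_field <- function(range, sigma) {
    if (sigma == 0) return(rep(0, nrow(domain$cells)))
    as.vector(A %*% sample_gmrf(spde_precision(mesh, range, sigma), 1L))
  }
  hum <- draw_field(field_params$humidity$range, field_params$humidity$sigma)
  years <- domain$years
  t_c <- years - mean(years)
  tab <- list()
  for (nm in c("bio01", "bio07", "bio16", "tpi")) {
    fp <- field_params[[nm]]
    base <- draw_field(fp$range, fp$sigma) + fp$mix * hum
    for (k in seq_along(years))
      tab[[length(tab) + 1L]] <- data.frame(cell_id = domain$cells$cell_id,
                                            year = years[k], name = nm,
                                            value = base + fp$trend * t_c[k])
  }
  # canopy composition: softmax of 4 fields (strata <3, 3-8, 8-15, >15 m)
  cf <- field_params$canopy
  Z <- vapply(1:4, function(i) draw_field(cf$range, cf$sigma), numeric(nrow(domain$cells)))
  Z[, 2] <- Z[, 2] + 0.8 * hum  # mid canopy denser in humid ravines
  E <- exp(Z - apply(Z, 1, max))
  P <- E / rowSums(E)
  colnames(P) <- c("canopy_below3", "canopy_3_8", "canopy_8_15", "canopy_above15")
  heights <- c(1.5, 5.5, 11.5, 18)
  rao_vert <- vapply(seq_len(nrow(P)), function(i) rao_q(heights, P[i, ]), 0)
  cover <- 1 - P[, 1]
  rao_horiz <- rao_q_window(domain, cover, window = 3L)
  ilr <- ilr_transform(P)
  static <- cbind(rao_vertical = rao_vert, rao_horizontal = rao_horiz,
                  ilr1 = ilr[, 1], ilr2 = ilr[, 2], ilr3 = ilr[, 3])
  # linear features: rivers and access roads crossing the domain
  rand_seg <- function() {
    side <- sample.int(4L, 2L)
    pt <- function(s) switch(s, cbind(stats::runif(1) * domain$extent, 0),
                             cbind(domain$extent, stats::runif(1) * domain$extent),
                             cbind(stats::runif(1) * domain$extent, domain$extent),
                             cbind(0, stats::runif(1) * domain$extent))
    rbind(pt(side[1]), pt(if (side[2] == side[1]) side[1] %% 4L + 1L else side[2]))
  }
  roads <- lapply(seq_len(field_params$n_roads), function(i) rand_seg())
  rivers <- lapply(seq_len(field_params$n_rivers), function(i) rand_seg())
  static <- cbind(static,
                  dist_river = distance_surface(rivers, domain),
                  log_road_dist = distance_surface(roads, domain, log = TRUE))
  for (cn in colnames(static)) for (k in seq_along(years))
    tab[[length(tab) + 1L]] <- data.frame(cell_id = domain$cells$cell_id,
                                          year = years[k], name = cn,
                                          value = static[, cn])
  list(table = do.call(rbind, tab), canopy = P, roads = roads, rivers = rivers,
       mesh = mesh)
}

#' Arrange a long covariate table as a [cell, year, name] array
#' @param covariates Long covariate table (cell_id, year, name, value).
#' @param domain A \code{fern_domain}.
#' @param names Covariate names to extract (default all).
#' @return 3-d array [n_cells, n_years, n_names].
#' @export
covariate_array <- function(covariates, domain, names = NULL) {
  if (is.null(names)) names <- unique(covariates$name)
  n_c <- nrow(domain$cells); n_t <- length(domain$years)
  arr <- array(NA_real_, c(n_c, n_t, length(names)),
               dimnames = list(NULL, domain$years, names))
  yi <- match(covariates$year, domain$years)
  ni <- match(covariates$name, names)
  ok <- !is.na(ni)
  arr[cbind(covariates$cell_id[ok], yi[ok], ni[ok])] <- covariates$value[ok]
  arr
}

#' Default generative hyperparameters
#'
#' Magnitudes give per-cell expected counts of a few to a few tens of
#' individuals inside populations; ranges sit between the cell size and the
#' domain extent so fields are resolvable on desk-scale meshes.
#'
#' @param domain A \code{fern_domain} (sets sensible ranges from its extent).
#' @return List of generative hyperparameters (class \code{fern_truth_hypers}).
#' @export
fern_truth_hypers <- function(domain = NULL) {
  ext <- if (is.null(domain)) 10000 else domain$extent
  list(
    u = list(range = ext / 3, sigma = 0.8, rho = 0.7),
    delta = list(range = ext / 5, sigma = 0.5, rho = 0.6),
    svc = list(range = ext / 6, sigma = 0.05, betas = c(1, 1.4, 0.7)),
    psi = 2,
    beta = c(bio01 = -0.3, tpi = -0.4, rao_vertical = 0.3, dist_river = -0.2),
    intercepts = c(-6.2, -6.6, -7.0)
  )
}

#' Simulate the latent fields and intensities of the generative model
#'
#' Draws the shared spatio-temporal field u(s,t) and species fields
#' delta_j(s,t) from Kronecker SPDE x AR(1) precisions, the year-trend field
#' omega(s) from an SPDE precision (species trends are exact linear scalings
#' of the first species' field), and assembles per-cell log-intensities
#' eta_j(s,t) = intercept_j + X beta + u + delta_j + beta_j omega T(s,t),
#' lambda = exp(eta).
#'
#' @param domain A \code{fern_domain}.
#' @param mesh A \code{fern_mesh} covering the domain.
#' @param truth_hypers See \code{fern_truth_hypers}.
#' @param seed Integer seed.
#' @param covariates Optional covariate long table (for the fixed effects).
#' @return Object of class \code{fern_truth}.
#' @export
simulate_latent_fields <- function(domain, mesh, truth_hypers = fern_truth_hypers(domain),
                                   seed = 1L, covariates = NULL) {
  th <- truth_hypers
  if (abs(th$u$rho) >= 1 || abs(th$delta$rho) >= 1) stop("|AR(1) rho| must be < 1")
  if (th$psi <= 0) stop("psi must be positive")
  set.seed(seed)
  mesh <- mesh_with_fem(mesh)
  n_nodes <- nrow(mesh$loc); n_t <- length(domain$years)
  draw_st <- function(p) {
    if (p$sigma == 0) return(matrix(0, n_nodes, n_t))
    Q <- kronecker_st_precision(spde_precision(mesh, p$range, p$sigma),
                                ar1_precision(n_t, p$rho))
    matrix(sample_gmrf(Q, 1L), n_nodes, n_t)
  }
  u <- draw_st(th$u)
  delta <- lapply(1:3, function(j) draw_st(th$delta))
  omega <- if (th$svc$sigma == 0) rep(0, n_nodes) else
    as.vector(sample_gmrf(spde_precision(mesh, th$svc$range, th$svc$sigma), 1L))
  A <- projector(mesh, as.matrix(domain$cells[, c("x", "y")]))
  t_c <- domain$years - mean(domain$years)
  n_c <- nrow(domain$cells)
  Xb <- matrix(0, n_c, n_t)
  if (!is.null(covariates) && length(th$beta)) {
    arr <- covariate_array(covariates, domain, names(th$beta))
    for (k in seq_along(th$beta)) Xb <- Xb + th$beta[k] * arr[, , k]
  }
  eta <- array(0, c(n_c, n_t, 3))
  Au <- as.matrix(A %*% u)
  Aom <- as.vector(A %*% omega)
  for (j in 1:3) {
    Ad <- as.matrix(A %*% delta[[j]])
    eta[, , j] <- th$intercepts[j] + Xb + Au + Ad +
      outer(Aom * th$svc$betas[j], t_c)
  }
  structure(list(domain = domain, mesh = mesh, hypers = th, u = u, delta = delta,
                 omega = omega, eta = eta, lambda = exp(eta),
                 covariates = covariates, A_cells = A, seed = seed),
            class = "fern_truth")
}

#' Simulate count and presence observations from a generative truth
#'
#' Population polygons (squares of realistic monitored area) are placed where
#' the species' intensity is high; per intersected cell and observed year,
#' counts are Poisson for species 1 and 3 and negative binomial for species 2
#' with mean area x intensity. Missing survey years are masked per population
#' by a rate drawn once from the missingness distribution. Presence locations
#' are sampled proportionally to intensity, thinned by a logistic
#' accessibility bias in log road distance, and replicated across all years
#' as timeless records.
#'
#' @param truth A \code{fern_truth}.
#' @param populations_spec List: \code{n_pops} (per species),
#'   \code{area_range_ha}, \code{area_median_ha}.
#' @param missing_spec List: \code{shape1}, \code{shape2}, \code{min},
#'   \code{max} of the per-population Beta missing-rate draw.
#' @param bias_spec List: \code{intercept}, \code{slope} of the logistic
#'   accessibility thinning in log road distance; \code{n_presence} per species.
#' @param seed Integer seed.
#' @return List: \code{counts}, \code{presences}, \code{populations} (meta),
#'   \code{polygons}, \code{missing_rates}.
#' @export
simulate_observations <- function(truth,
                                  populations_spec = list(n_pops = c(22L, 17L, 11L),
                                                          area_range_ha = c(0.11, 3.81),
                                                          area_median_ha = 0.68),
                                  missing_spec = list(shape1 = 2, shape2 = 5.2,
                                                      min = 0.0714, max = 0.818),
                                  bias_spec = list(intercept = 2, slope = -0.8,
                                                   n_presence = c(24L, 13L, 10L)),
                                  seed = 1L) {
  set.seed(seed)
  domain <- truth$domain
  n_t <- length(domain$years)
  lam_bar <- apply(truth$lambda, c(1, 3), mean)
  cs <- domain$cell_size
  polys <- list(); meta <- list(); counts <- list(); miss_rates <- numeric(0)
  pid <- 0L
  for (j in 1:3) {
    w <- lam_bar[, j]
    for (p in seq_len(populations_spec$n_pops[j])) {
      pid <- pid + 1L
      name <- sprintf("P%02d", pid)
      # monitored area: lognormal around the median, truncated to the range
      repeat {
        a_ha <- exp(stats::rnorm(1, log(populations_spec$area_median_ha), 0.6))
        if (a_ha >= populations_spec$area_range_ha[1] &&
            a_ha <= populations_spec$area_range_ha[2]) break
      }
      side <- sqrt(a_ha * 1e4)
      cell <- if (sum(w) > 0) sample.int(length(w), 1L, prob = w) else
        sample.int(length(w), 1L)
      cx <- min(max(domain$cells$x[cell] + stats::runif(1, -cs / 2, cs / 2), side / 2),
                domain$extent - side / 2)
      cy <- min(max(domain$cells$y[cell] + stats::runif(1, -cs / 2, cs / 2), side / 2),
                domain$extent - side / 2)
      poly <- cbind(cx + c(-1, 1, 1, -1) * side / 2, cy + c(-1, -1, 1, 1) * side / 2)
      polys[[name]] <- poly
      meta[[name]] <- data.frame(population = name, species = j, area_ha = a_ha,
                                 cx = cx, cy = cy)
      # missingness mask drawn once per population
      repeat {
        pm <- stats::rbeta(1, missing_spec$shape1, missing_spec$shape2)
        if (pm >= missing_spec$min && pm <= missing_spec$max) break
      }
      miss_rates[name] <- pm
      missing_years <- stats::runif(n_t) < pm
      if (all(missing_years)) missing_years[sample.int(n_t, 1L)] <- FALSE
      ca <- population_cell_areas(poly, domain)
      for (k in seq_len(n_t)) {
        lam <- truth$lambda[ca$cell_id, k, j]
        mu <- ca$area * lam
        y <- if (missing_years[k]) rep(NA_integer_, nrow(ca)) else if (j == 2L)
          stats::rnbinom(nrow(ca), size = truth$hypers$psi, mu = mu) else
            stats::rpois(nrow(ca), mu)
        counts[[length(counts) + 1L]] <-
          data.frame(species = j, population = name, cell_id = ca$cell_id,
                     year = domain$years[k], count = y, area_m2 = ca$area,
                     missing = missing_years[k])
      }
    }
  }
  counts <- do.call(rbind, counts)
  # presence locations: intensity-weighted, thinned by road accessibility
  lrd <- if (!is.null(truth$covariates))
    covariate_array(truth$covariates, domain, "log_road_dist")[, 1, 1] else
      rep(0, nrow(domain$cells))
  keep_p <- stats::plogis(bias_spec$intercept + bias_spec$slope * lrd)
  pres <- list()
  for (j in 1:3) {
    w <- lam_bar[, j] * keep_p
    n_j <- min(bias_spec$n_presence[j], sum(w > 0))
    if (n_j == 0L) next
    cells <- sample.int(length(w), n_j, prob = w)
    pres[[j]] <- data.frame(species = j,
                            cell_id = rep(cells, each = n_t),
                            year = rep(domain$years, times = n_j),
                            present = 1L,
                            log_road_dist = rep(lrd[cells], each = n_t))
  }
  presences <- if (length(pres)) do.call(rbind, pres) else
    data.frame(species = integer(0), cell_id = integer(0), year = integer(0),
               present = integer(0), log_road_dist = numeric(0))
  list(counts = counts, presences = presences,
       populations = do.call(rbind, meta), polygons = polys,
       missing_rates = miss_rates)
}

#' Generate a complete synthetic study dataset
#'
#' Orchestrates domain, mesh, covariates, latent truth and observations with
#' seeds derived deterministically from one root seed.
#'
#' @param seed Root seed.
#' @param extent_m,cell_size_m,n_years,year_start Domain parameters.
#' @param truth_hypers,field_params,populations_spec,missing_spec,bias_spec
#'   Passed through to the stage generators (defaults mirror the study shape).
#' @param mesh_edge Inner maximum mesh edge (default extent/10).
#' @return List: domain, mesh, covariates, truth, obs.
#' @export
fern_simulate <- function(seed = 1L, extent_m = 10000, cell_size_m = 100,
                          n_years = 10L, year_start = 2014L,
                          truth_hypers = NULL, field_params = fern_field_params(),
                          populations_spec = list(n_pops = c(22L, 17L, 11L),
                                                  area_range_ha = c(0.11, 3.81),
                                                  area_median_ha = 0.68),
                          missing_spec = list(shape1 = 2, shape2 = 5.2,
                                              min = 0.0714, max = 0.818),
                          bias_spec = list(intercept = 2, slope = -0.8,
                                           n_presence = c(24L, 13L, 10L)),
                          mesh_edge = NULL) {
  domain <- generate_domain(seed, extent_m, cell_size_m, n_years, year_start)
  if (is.null(mesh_edge)) mesh_edge <- extent_m / 10
  mesh <- mesh_with_fem(build_mesh(domain, max_edge_inner = mesh_edge,
                                   max_edge_outer = 2 * mesh_edge,
                                   extension = extent_m / 5,
                                   cutoff = mesh_edge / 10))
  if (is.null(truth_hypers)) truth_hypers <- fern_truth_hypers(domain)
  covs <- generate_covariates(domain, seed = seed + 1L,
                              field_params = field_params, mesh = mesh)
  truth <- simulate_latent_fields(domain, mesh, truth_hypers, seed = seed + 2L,
                                  covariates = covs$table)
  obs <- simulate_observations(truth, populations_spec, missing_spec, bias_spec,
                               seed = seed + 3L)
  list(domain = domain, mesh = mesh, covariates = covs, truth = truth, obs = obs)
}

#' Write a simulated dataset to a directory
#'
#' counts.csv and presences.csv (observation schemas), populations.geojson,
#' covariates.csv (long gridded table), truth.yaml (generative
#' hyperparameters) and truth fields as CSV arrays.
#'
#' @param sim Output of \code{fern_simulate}.
#' @param dir Target directory (created).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.csv"),
    presences = file.path(dir, "presences.csv"),
    populations = file.path(dir, "populations.geojson"),
    covariates = file.path(dir, "covariates.csv"),
    truth = file.path(dir, "truth.yaml"),
    u = file.path(dir, "truth_u.csv"))
  utils::write.csv(sim$obs$counts, paths["counts"], row.names = FALSE)
  utils::write.csv(sim$obs$presences, paths["presences"], row.names = FALSE)
  write_polygons_geojson(sim$obs$polygons, paths["populations"],
                         meta = sim$obs$populations)
  utils::write.csv(sim$covariates$table, paths["covariates"], row.names = FALSE)
  yaml::write_yaml(sim$truth$hypers, paths["truth"])
  utils::write.csv(as.data.frame(sim$truth$u), paths["u"], row.names = FALSE)
  invisible(paths)
}
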