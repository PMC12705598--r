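# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

# small desk-scale simulated study: 10x10 grid of 150 m cells, 8 years,
# 18 populations, coarse mesh (49 nodes)
small_sim <- function() {
  if (is.null(.fix$sim)) {
    .fix$sim <- fern_simulate(
      seed = 11, extent_m = 1500, cell_size_m = 150, n_years = 8,
      mesh_edge = 500,
      populations_spec = list(n_pops = c(8L, 6L, 4L),
                              area_range_ha = c(0.11, 3.81),
                              area_median_ha = 0.68))
  }
  .fix$sim
}

small_data <- function(covariate_names = c("bio01", "tpi"), presences = FALSE) {
  sim <- small_sim()
  out <- list(domain = sim$domain, mesh = sim$mesh,
              covariates = sim$covariates$table, counts = sim$obs$counts,
              covariate_names = covariate_names)
  if (presences) out$presences <- sim$obs$presences
  out
}

# a fitted M1 (no hyperparameters, fast) on the small study
small_fit_m1 <- function() {
  if (is.null(.fix$fit_m1))
    .fix$fit_m1 <- fit_isdm(make_configs()$M1, small_data(), seed = 1)
  .fix$fit_m1
}

# a fitted M21 (tied species hyperparameters) on the small study
small_fit_m21 <- function() {
  if (is.null(.fix$fit_m21))
    .fix$fit_m21 <- fit_isdm(
      make_configs()$M21, small_data(),
      options = fit_options(tie_species_hypers = TRUE, outer_maxit = 120L),
      seed = 1)
  .fix$fit_m21
}

# tiny two-species toy used for scalar likelihood oracles
toy_model_data <- function(config) {
  domain <- generate_domain(1, extent_m = 200, cell_size_m = 100, n_years = 2)
  mesh <- mesh_with_fem(build_mesh(domain, max_edge_inner = 150,
                                   max_edge_outer = 300, extension = 100,
                                   cutoff = 10))
  covs <- rbind(
    expand.grid(cell_id = 1:4, year = domain$years, name = "x1"),
    expand.grid(cell_id = 1:4, year = domain$years, name = "log_road_dist"))
  covs$value <- c(seq(-0.3, 0.4, length.out = 8), rep(c(3, 4, 5, 6), 2))
  counts <- data.frame(species = c(1L, 1L, 2L, 2L),
                       population = c("A", "A", "B", "B"),
                       cell_id = c(1L, 1L, 3L, 3L),
                       year = rep(domain$years, 2),
                       count = c(2L, 5L, 1L, 0L),
                       area_m2 = c(400, 400, 900, 900), missing = FALSE)
  presences <- data.frame(species = c(1L, 2L), cell_id = c(2L, 4L),
                          year = domain$years[1], present = 1L,
                          log_road_dist = c(4, 6))
  list(domain = domain, mesh = mesh, covariates = covs, counts = counts,
       presences = presences, config = config)
}
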