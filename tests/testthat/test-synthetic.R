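test_that("fixed seeds reproduce every synthetic output bit-identically", {
  a <- fern_simulate(seed = 3, extent_m = 1000, cell_size_m = 100, n_years = 3,
                     mesh_edge = 400,
                     populations_spec = list(n_pops = c(3L, 2L, 2L),
                                             area_range_ha = c(0.11, 3.81),
                                             area_median_ha = 0.68))
  b <- fern_simulate(seed = 3, extent_m = 1000, cell_size_m = 100, n_years = 3,
                     mesh_edge = 400,
                     populations_spec = list(n_pops = c(3L, 2L, 2L),
                                             area_range_ha = c(0.11, 3.81),
                                             area_median_ha = 0.68))
  expect_identical(a$obs$counts, b$obs$counts)
  expect_identical(a$obs$presences, b$obs$presences)
  expect_identical(a$truth$u, b$truth$u)
  expect_identical(a$covariates$table$value, b$covariates$table$value)
})

test_that("canopy strata close to one and zero-variance fields are constant", {
  sim <- small_sim()
  expect_equal(unname(rowSums(sim$covariates$canopy)), rep(1, 100),
               tolerance = 1e-12)
  expect_true(all(sim$covariates$canopy >= 0))
  d <- generate_domain(1, 600, 100, 2)
  fp <- fern_field_params()
  fp$bio01$sigma <- 0; fp$bio01$mix <- 0; fp$bio01$trend <- 0
  cv <- generate_covariates(d, seed = 2, field_params = fp)
  v <- cv$table$value[cv$table$name == "bio01"]
  expect_equal(max(v) - min(v), 0)
  fp$bio07$sigma <- -1
  expect_error(generate_covariates(d, seed = 2, field_params = fp),
               "negative variance")
})

test_that("generated fields have the requested effective correlation range", {
  d <- generate_domain(1, 2000, 100, 2)
  fp <- fern_field_params()
  fp$bio16 <- list(range = 600, sigma = 1, trend = 0, mix = 0)
  vals <- sapply(1:50, function(s) {
    cv <- generate_covariates(d, seed = 100 + s, field_params = fp)
    cv$table$value[cv$table$name == "bio16" & cv$table$year == d$years[1]]
  })
  # cross-replicate correlogram along the x axis, averaged over all
  # same-row cell pairs at each lag
  nx <- d$nx
  lags <- seq_len(12)
  corrs <- sapply(lags, function(L) {
    cs <- unlist(lapply(seq_len(nx), function(iy) {
      base <- (iy - 1) * nx
      sapply(seq_len(nx - L), function(ix)
        cor(vals[base + ix, ], vals[base + ix + L, ]))
    }))
    mean(cs)
  })
  dists <- lags * d$cell_size
  below <- which(corrs <= 0.13)[1]
  est_range <- dists[below - 1] +
    (0.13 - corrs[below - 1]) / (corrs[below] - corrs[below - 1]) *
      (dists[below] - dists[below - 1])
  expect_lt(abs(est_range - 600), 0.25 * 600)
})

test_that("latent field simulation honors degenerate and scaling structure", {
  sim <- small_sim()
  th0 <- sim$truth$hypers
  th0$u$sigma <- 0
  tr <- simulate_latent_fields(sim$domain, sim$mesh, th0, seed = 5,
                               covariates = sim$covariates$table)
  expect_equal(max(abs(tr$u)), 0)  # sd = 0 -> identically zero field
  # trend fields of species 2 and 3 are exact linear scalings of species 1
  b <- tr$hypers$svc$betas
  w1 <- tr$omega * b[1]; w2 <- tr$omega * b[2]
  expect_equal(abs(cor(w1, w2)), 1, tolerance = 1e-12)
  expect_error(simulate_latent_fields(sim$domain, sim$mesh,
                                      modifyList(th0, list(psi = -1)),
                                      seed = 1),
               "psi")
})

test_that("the shared field's lag-1 temporal autocorrelation matches rho", {
  sim <- small_sim()
  n_t <- length(sim$domain$years)
  rho <- 0.6
  Q <- kronecker_st_precision(spde_precision(sim$mesh, 600, 1),
                              ar1_precision(n_t, rho))
  set.seed(31)
  X <- sample_gmrf(Q, 200)
  n_nodes <- nrow(sim$mesh$loc)
  F <- array(X, c(n_nodes, n_t, 200))
  # per-node, per-replicate lag-1 correlation across the 200 replicates
  a <- F[, 1:(n_t - 1), ]
  b <- F[, 2:n_t, ]
  expect_equal(cor(as.vector(a), as.vector(b)), rho, tolerance = 0.05)
})

test_that("zero intensity yields no counts and no presences", {
  sim <- small_sim()
  tr <- sim$truth
  tr$lambda[] <- 0
  obs <- simulate_observations(tr, seed = 9)
  expect_true(all(obs$counts$count[!obs$counts$missing] == 0))
  expect_equal(nrow(obs$presences), 0)
})

test_that("counts are mean-calibrated to area times intensity", {
  sim <- small_sim()
  cnt <- sim$obs$counts[!sim$obs$counts$missing, ]
  yix <- match(cnt$year, sim$domain$years)
  mu <- cnt$area_m2 *
    sim$truth$lambda[cbind(cnt$cell_id, yix, cnt$species)]
  pois <- cnt$species != 2L
  z <- (cnt$count[pois] - mu[pois]) / sqrt(mu[pois])
  # mean Pearson residual is 0 within Monte-Carlo error
  expect_lt(abs(mean(z)) * sqrt(sum(pois)), 4)
})

test_that("the overdispersed species is NegBin and approaches Poisson as psi
          grows", {
  sim <- small_sim()
  pearson_var <- function(psi, seeds) {
    tr <- sim$truth
    tr$hypers$psi <- psi
    tr$lambda <- tr$lambda * 30  # keep cell means away from degeneracy
    z <- unlist(lapply(seeds, function(s) {
      obs <- simulate_observations(
        tr, populations_spec = list(n_pops = c(0L, 60L, 0L),
                                    area_range_ha = c(0.11, 3.81),
                                    area_median_ha = 0.68), seed = s)
      cnt <- obs$counts[!obs$counts$missing, ]
      yix <- match(cnt$year, sim$domain$years)
      mu <- cnt$area_m2 * tr$lambda[cbind(cnt$cell_id, yix, cnt$species)]
      keep <- mu > 0.5  # Pearson residuals degenerate at near-zero means
      (cnt$count[keep] - mu[keep]) / sqrt(mu[keep])
    }))
    c(v = stats::var(z), n = length(z))
  }
  lo <- pearson_var(0.4, 1:15)
  hi <- pearson_var(1e6, 1:15)
  expect_gt(lo["n"], 5e3)
  expect_gt(lo["v"], 2)        # variance > mean at small psi
  expect_equal(unname(hi["v"]), 1, tolerance = 0.15)  # Poisson limit
})

test_that("presence records replicate timelessly across years", {
  sim <- fern_simulate(seed = 21, extent_m = 2000, cell_size_m = 100,
                       n_years = 10, mesh_edge = 600,
                       populations_spec = list(n_pops = c(6L, 5L, 4L),
                                               area_range_ha = c(0.11, 3.81),
                                               area_median_ha = 0.68))
  pres <- sim$obs$presences
  locs <- unique(pres[, c("species", "cell_id")])
  expect_equal(nrow(pres), nrow(locs) * 10)
  per_loc <- table(paste(pres$species, pres$cell_id))
  expect_true(all(per_loc == 10))  # constant across years
  # default shape: 24 + 13 + 10 = 47 locations -> 470 records
  expect_equal(nrow(locs), 47)
  expect_equal(nrow(pres), 470)
})

test_that("population polygons have realistic monitored areas and missingness", {
  sim <- small_sim()
  areas <- sim$obs$populations$area_ha
  expect_true(all(areas >= 0.11 & areas <= 3.81))
  expect_equal(nrow(sim$obs$populations), 18)
  expect_true(all(sim$obs$missing_rates >= 0.0714 &
                    sim$obs$missing_rates <= 0.818))
  # every population keeps at least one observed year
  obs_by_pop <- tapply(!sim$obs$counts$missing, sim$obs$counts$population, any)
  expect_true(all(obs_by_pop))
})
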