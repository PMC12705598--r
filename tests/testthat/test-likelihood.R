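test_that("predictor assembly is additive, linear, and dimension-checked", {
  toy <- toy_model_data(make_configs()$M13)
  md <- build_model_data(toy$config, toy$domain, toy$mesh, toy$covariates,
                         toy$counts, toy$presences,
                         covariate_names = "x1",
                         presence_mode = "presence_only")
  lay <- md$layout
  eta0 <- assemble_predictor(toy$config, numeric(lay$n), md)
  expect_equal(max(abs(eta0)), 0)  # all-zero state -> eta == 0
  # adding c to a fixed coefficient shifts eta by c * X everywhere
  x <- numeric(lay$n)
  eta_a <- assemble_predictor(toy$config, x, md)
  x[1] <- x[1] + 2.5
  eta_b <- assemble_predictor(toy$config, x, md)
  # reconstruct x1 values per likelihood row
  rows <- rbind(
    data.frame(cell_id = toy$counts$cell_id, year = toy$counts$year),
    data.frame(cell_id = md$presence_table$cell_id,
               year = md$presence_table$year))
  x1 <- covariate_array(toy$covariates, toy$domain, "x1")
  vals <- x1[cbind(rows$cell_id, match(rows$year, toy$domain$years), 1L)]
  expect_equal(as.numeric(eta_b - eta_a), 2.5 * vals, tolerance = 1e-12)
  expect_error(assemble_predictor(toy$config, numeric(3), md), "length")
  expect_error(assemble_predictor(toy$config, list(nope = 1), md), "not active")
})

test_that("a single observation with all components active matches scalar
          arithmetic", {
  cfg <- fern_config(model = NULL, data_fusion = FALSE, joint_structure = TRUE,
                     shared_fixed = TRUE, shared_st = TRUE, species_st = TRUE,
                     svc = TRUE)
  toy <- toy_model_data(cfg)
  md <- build_model_data(cfg, toy$domain, toy$mesh, toy$covariates,
                         toy$counts[1, ], covariate_names = "x1")
  lay <- md$layout
  set.seed(8)
  x <- rnorm(lay$n)
  b <- c(1.3, 0.4)
  eta <- assemble_predictor(cfg, x, md, b = b)
  # by hand: beta * x1 + intercept_1 + A u(.,t1) + A delta_1(.,t1) + A omega * T
  A <- md$A_cells[toy$counts$cell_id[1], , drop = FALSE]
  nn <- md$n_nodes
  g <- function(nm) x[lay$blocks[[nm]]$start + seq_len(lay$blocks[[nm]]$length) - 1]
  tc <- md$t_c[1]
  hand <- g("beta")[1] * covariate_array(toy$covariates, toy$domain, "x1")[
    toy$counts$cell_id[1], 1, 1] +
    g("intercept")[1] +
    sum(A * g("u")[seq_len(nn)]) +
    sum(A * g("delta1")[seq_len(nn)]) +
    sum(A * g("omega")) * tc  # species 1: scaling fixed at 1
  expect_equal(eta[1], hand, tolerance = 1e-12)
})

test_that("count log-likelihood matches closed forms and the offset law", {
  obs <- data.frame(species = 1L, count = 2L, area_m2 = 1, missing = FALSE)
  expect_equal(loglik_counts(obs, log(3)), 2 * log(3) - 3 - log(2))
  # doubling the sampled area adds log 2 to log mu exactly
  obs2 <- obs; obs2$area_m2 <- 2
  eta <- 0.7
  expect_equal(exp(log(obs2$area_m2) + eta) / exp(log(obs$area_m2) + eta), 2)
  expect_equal(loglik_counts(obs2, eta),
               dpois(2, 2 * exp(eta), log = TRUE))
  # NegBin at psi = 1e6 matches Poisson within 1e-4
  obs_nb <- data.frame(species = 2L, count = 7L, area_m2 = 10, missing = FALSE)
  expect_equal(loglik_counts(obs_nb, 0.3, psi = 1e6),
               dpois(7L, 10 * exp(0.3), log = TRUE), tolerance = 1e-4)
  # missing records contribute zero
  obs_m <- rbind(obs, data.frame(species = 1L, count = NA, area_m2 = 1,
                                 missing = TRUE))
  expect_equal(loglik_counts(obs_m, c(log(3), 99)), loglik_counts(obs, log(3)))
  expect_error(loglik_counts(data.frame(species = 1L, count = -1L, area_m2 = 1,
                                        missing = FALSE), 0), "negative")
})

test_that("presence log-likelihood follows the cloglog link exactly", {
  expect_equal(1 - exp(-exp(0)), 0.6321206, tolerance = 1e-6)
  o1 <- data.frame(present = 1L)
  expect_equal(loglik_presence(o1, 0), log(1 - exp(-1)))
  o0 <- data.frame(present = 0L)
  eta <- 0.4
  expect_equal(loglik_presence(o0, eta), -exp(eta))  # cloglog complement
  set.seed(10)
  y <- rbinom(50, 1, 0.5)
  eta <- rnorm(50)
  p <- 1 - exp(-exp(eta))
  oracle <- sum(dbinom(y, 1, p, log = TRUE))
  expect_equal(loglik_presence(data.frame(present = y), eta), oracle,
               tolerance = 1e-12)
  expect_warning(loglik_presence(o1, -50), "clamped")
  # presence probability is monotone increasing in eta
  grid <- seq(-5, 3, length.out = 100)
  expect_true(all(diff(1 - exp(-exp(grid))) > 0))
})

test_that("the joint likelihood decomposes additively and matches a
          from-scratch oracle", {
  cfg <- make_configs()$M13
  toy <- toy_model_data(cfg)
  md <- build_model_data(cfg, toy$domain, toy$mesh, toy$covariates,
                         toy$counts, toy$presences, covariate_names = "x1",
                         presence_mode = "presence_only")
  lay <- md$layout
  set.seed(11)
  x <- rnorm(lay$n) * 0.3
  hypers <- list(u = list(range = 400, sigma = 1, rho = 0.5),
                 delta = list(range = 300, sigma = 0.8, rho = 0.4),
                 psi = 2)
  jl <- joint_loglik(cfg, x, hypers, md)
  br <- attr(jl, "breakdown")
  expect_equal(as.numeric(jl), sum(br), tolerance = 1e-12)
  # count term equals the exposed count log-likelihood on the same eta
  eta <- assemble_predictor(cfg, x, md)
  etac <- eta[md$lik$type == "count"]
  expect_equal(unname(br["counts"]),
               loglik_counts(toy$counts, etac, psi = 2), tolerance = 1e-12)
  expect_equal(unname(br["presence"]),
               loglik_presence(md$presence_table,
                               eta[md$lik$type == "presence"]),
               tolerance = 1e-12)
  # GMRF term equals the dense multivariate-normal log density
  Q <- fernfusion:::prior_precision(md, hypers)
  dense <- -0.5 * as.numeric(t(x) %*% as.matrix(Q) %*% x) +
    0.5 * determinant(as.matrix(Q), logarithm = TRUE)$modulus[[1]] -
    0.5 * lay$n * log(2 * pi)
  expect_equal(unname(br["gmrf"]), dense, tolerance = 1e-8)
  # fusion off -> presence term exactly absent, with a warning
  cfg21 <- make_configs()$M21
  expect_warning(
    md2 <- build_model_data(cfg21, toy$domain, toy$mesh, toy$covariates,
                            toy$counts, toy$presences,
                            covariate_names = "x1"),
    "ignored")
  jl2 <- joint_loglik(cfg21, numeric(md2$layout$n), hypers, md2)
  expect_equal(unname(attr(jl2, "breakdown")["presence"]), 0)
})

test_that("eta and likelihood terms are invariant to observation order", {
  cfg <- make_configs()$M21
  toy <- toy_model_data(cfg)
  perm <- c(3, 1, 4, 2)
  md_a <- build_model_data(cfg, toy$domain, toy$mesh, toy$covariates,
                           toy$counts, covariate_names = "x1")
  md_b <- build_model_data(cfg, toy$domain, toy$mesh, toy$covariates,
                           toy$counts[perm, ], covariate_names = "x1")
  hypers <- list(u = list(range = 400, sigma = 1, rho = 0.5),
                 delta = list(range = 300, sigma = 0.8, rho = 0.4), psi = 2)
  set.seed(12)
  x <- rnorm(md_a$layout$n) * 0.2
  expect_equal(as.numeric(joint_loglik(cfg, x, hypers, md_a)),
               as.numeric(joint_loglik(cfg, x, hypers, md_b)),
               tolerance = 1e-12)
})
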