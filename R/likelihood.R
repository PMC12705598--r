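# Assembly of the latent predictor and the joint likelihood.
#
# Latent vector layout (blocks present only when the configuration activates
# them): fixed-effect coefficients (shared, or one block per species), count
# intercept(s), shared spatio-temporal field u (node-major within year),
# species fields delta_j, shared spatial field, year-trend field omega,
# presence intercepts, road-distance coefficient gamma. The cross-species
# trend scalings b_2, b_3 multiply omega's design columns and are
# hyperparameters, so the observation design is H = H0 + b2 H_svc2 + b3 H_svc3.

FAM_POISSON <- 1L; FAM_NEGBIN <- 2L; FAM_BERNOULLI <- 3L

#' Latent vector layout for a configuration
#' @keywords internal
latent_layout <- function(config, n_cov, n_nodes, n_years, fusion_active) {
  blocks <- list()
  add <- function(blocks, name, len) {
    start <- if (length(blocks)) blocks[[length(blocks)]]$start +
      blocks[[length(blocks)]]$length else 1L
    blocks[[name]] <- list(name = name, start = start, length = as.integer(len))
    blocks
  }
  if (n_cov > 0) {
    if (config$shared_fixed) blocks <- add(blocks, "beta", n_cov)
    else blocks <- add(blocks, "beta", 3L * n_cov)
  }
  blocks <- add(blocks, "intercept", if (config$joint_structure) 3L else 1L)
  if (config$shared_st) blocks <- add(blocks, "u", n_nodes * n_years)
  if (config$species_st) for (j in 1:3)
    blocks <- add(blocks, paste0("delta", j), n_nodes * n_years)
  if (config$spatial_spde) blocks <- add(blocks, "spatial", n_nodes)
  if (config$svc) blocks <- add(blocks, "omega", n_nodes)
  if (fusion_active) {
    blocks <- add(blocks, "pres_intercept", 3L)
    blocks <- add(blocks, "gamma_road", 1L)
  }
  n <- if (length(blocks)) blocks[[length(blocks)]]$start +
    blocks[[length(blocks)]]$length - 1L else 0L
  list(blocks = blocks, n = n)
}

#' @keywords internal
block_idx <- function(layout, name) {
  b <- layout$blocks[[name]]
  if (is.null(b)) return(integer(0))
  b$start + seq_len(b$length) - 1L
}

#' Build sparse design matrices for a set of observation rows
#'
#' @keywords internal
make_design <- function(md, species, cell_id, year_idx, type, road = NULL) {
  cfg <- md$config; lay <- md$layout
  n <- length(species)
  n_nodes <- md$n_nodes; n_years <- length(md$years)
  ti <- tj <- tx <- list()   # triplets for H0
  s2i <- s2j <- s2x <- list(); s3i <- s3j <- s3x <- list()
  push <- function(i, j, x) {
    m <- max(length(i), length(j), length(x))
    ti[[length(ti) + 1L]] <<- rep_len(i, m); tj[[length(tj) + 1L]] <<- rep_len(j, m)
    tx[[length(tx) + 1L]] <<- rep_len(x, m)
  }
  p <- length(md$covariate_names)
  if (p > 0) {
    b <- lay$blocks$beta
    Xv <- md$cov_arr[cbind(rep(cell_id, p), rep(year_idx, p),
                           rep(seq_len(p), each = n))]
    Xv <- matrix(Xv, n, p)
    for (k in seq_len(p)) {
      col <- if (cfg$shared_fixed) b$start + k - 1L else
        b$start + (species - 1L) * p + k - 1L
      push(seq_len(n), col, Xv[, k])
    }
  }
  if (type == "count" || !cfg$joint_structure) {
    ib <- lay$blocks$intercept
    col <- if (cfg$joint_structure) ib$start + species - 1L else rep(ib$start, n)
    if (type == "count") push(seq_len(n), col, rep(1, n))
  }
  # presence rows in a pooled (non-joint) model share the global intercept
  if (type == "presence" && !cfg$joint_structure) {
    ib <- lay$blocks$intercept
    push(seq_len(n), rep(ib$start, n), rep(1, n))
  }
  At <- methods::as(md$A_cells[cell_id, , drop = FALSE], "TsparseMatrix")
  ai <- At@i + 1L; aj <- At@j + 1L; ax <- At@x
  if (cfg$shared_st) {
    u0 <- lay$blocks$u$start
    push(ai, u0 + (year_idx[ai] - 1L) * n_nodes + aj - 1L, ax)
  }
  if (cfg$species_st) {
    for (j in 1:3) {
      sel <- species[ai] == j
      if (any(sel)) {
        d0 <- lay$blocks[[paste0("delta", j)]]$start
        push(ai[sel], d0 + (year_idx[ai[sel]] - 1L) * n_nodes + aj[sel] - 1L,
             ax[sel])
      }
    }
  }
  if (cfg$spatial_spde) {
    s0 <- lay$blocks$spatial$start
    push(ai, s0 + aj - 1L, ax)
  }
  if (cfg$svc) {
    w0 <- lay$blocks$omega$start
    tt <- md$t_c[year_idx]
    for (j in 1:3) {
      sel <- species[ai] == j
      if (!any(sel)) next
      trip <- list(i = ai[sel], j = w0 + aj[sel] - 1L, x = ax[sel] * tt[ai[sel]])
      if (j == 1L) push(trip$i, trip$j, trip$x)
      else if (j == 2L) { s2i[[length(s2i) + 1L]] <- trip$i
        s2j[[length(s2j) + 1L]] <- trip$j; s2x[[length(s2x) + 1L]] <- trip$x }
      else { s3i[[length(s3i) + 1L]] <- trip$i
        s3j[[length(s3j) + 1L]] <- trip$j; s3x[[length(s3x) + 1L]] <- trip$x }
    }
  }
  if (type == "presence" && cfg$joint_structure && md$fusion_active) {
    pb <- lay$blocks$pres_intercept
    push(seq_len(n), pb$start + species - 1L, rep(1, n))
  }
  if (type == "presence" && md$fusion_active) {
    gb <- lay$blocks$gamma_road
    push(seq_len(n), rep(gb$start, n), road)
  }
  mk <- function(ii, jj, xx)
    Matrix::sparseMatrix(i = as.integer(unlist(ii) %||% integer(0)),
                         j = as.integer(unlist(jj) %||% integer(0)),
                         x = as.numeric(unlist(xx) %||% numeric(0)),
                         dims = c(n, lay$n))
  list(H0 = mk(ti, tj, tx),
       Hsvc2 = if (cfg$svc) mk(s2i, s2j, s2x) else NULL,
       Hsvc3 = if (cfg$svc) mk(s3i, s3j, s3x) else NULL)
}

#' Prepare model data for fitting
#'
#' Joins observations with covariates, expands presence data to Bernoulli
#' trials, and builds the sparse observation design.
#'
#' @param config A \code{fern_config}.
#' @param domain,mesh Domain and mesh.
#' @param covariates Long covariate table (cell_id, year, name, value).
#' @param counts Count observations (schema of \code{redistribute_counts}).
#' @param presences Presence records (schema of \code{simulate_observations});
#'   ignored (with a warning) when the configuration has no data fusion.
#' @param covariate_names Names entering the fixed effects.
#' @param presence_mode \code{"all_cells"}: every domain cell enters as a
#'   Bernoulli trial each year (1 where a record falls); \code{"presence_only"}:
#'   only the recorded presence rows enter (the bookkeeping that counts 47
#'   locations x 10 years as 470 observations).
#' @param road_name Covariate supplying the presence-observation bias term.
#' @return A model-data list consumed by \code{fit_isdm} and the likelihood
#'   functions.
#' @export
build_model_data <- function(config, domain, mesh, covariates, counts,
                             presences = NULL,
                             covariate_names = character(0),
                             presence_mode = c("all_cells", "presence_only"),
                             road_name = "log_road_dist") {
  presence_mode <- match.arg(presence_mode)
  mesh <- mesh_with_fem(mesh)
  if (!config$data_fusion && !is.null(presences) && nrow(presences) > 0) {
    warning("config has no data fusion: presence records ignored")
    presences <- NULL
  }
  fusion_active <- config$data_fusion && !is.null(presences) && nrow(presences) > 0
  n_nodes <- nrow(mesh$loc)
  lay <- latent_layout(config, length(covariate_names), n_nodes,
                       length(domain$years), fusion_active)
  cov_arr <- covariate_array(covariates, domain,
                             unique(c(covariate_names, road_name)))
  md <- list(config = config, domain = domain, mesh = mesh, years = domain$years,
             t_c = domain$years - mean(domain$years),
             covariate_names = covariate_names,
             cov_arr = cov_arr[, , covariate_names, drop = FALSE],
             layout = lay, n_nodes = n_nodes,
             A_cells = projector(mesh, as.matrix(domain$cells[, c("x", "y")])),
             fusion_active = fusion_active, counts = counts)
  obs <- counts[!counts$missing, , drop = FALSE]
  yix <- match(obs$year, domain$years)
  if (any(is.na(yix))) stop("count year outside the domain's year range")
  fam <- if (config$joint_structure)
    c(FAM_POISSON, FAM_NEGBIN, FAM_POISSON)[obs$species] else
      rep(FAM_POISSON, nrow(obs))
  dz <- make_design(md, obs$species, obs$cell_id, yix, "count")
  lik <- list(y = obs$count, family = fam, offset = log(obs$area_m2),
              species = obs$species, type = rep("count", nrow(obs)),
              population = obs$population,
              H0 = dz$H0, Hsvc2 = dz$Hsvc2, Hsvc3 = dz$Hsvc3)
  if (fusion_active) {
    road_all <- cov_arr[, 1, road_name]
    if (presence_mode == "all_cells") {
      n_c <- nrow(domain$cells); n_t <- length(domain$years)
      grid <- expand.grid(cell_id = seq_len(n_c), year = domain$years,
                          species = 1:3)
      key <- paste(grid$species, grid$cell_id, grid$year)
      hit <- paste(presences$species, presences$cell_id, presences$year)
      grid$present <- as.integer(key %in% hit)
      pr <- grid
    } else {
      pr <- presences[, c("species", "cell_id", "year", "present")]
    }
    pyix <- match(pr$year, domain$years)
    pd <- make_design(md, pr$species, pr$cell_id, pyix, "presence",
                      road = road_all[pr$cell_id])
    lik$y <- c(lik$y, pr$present)
    lik$family <- c(lik$family, rep(FAM_BERNOULLI, nrow(pr)))
    lik$offset <- c(lik$offset, rep(0, nrow(pr)))
    lik$species <- c(lik$species, pr$species)
    lik$type <- c(lik$type, rep("presence", nrow(pr)))
    lik$population <- c(lik$population, rep(NA_character_, nrow(pr)))
    lik$H0 <- rbind(lik$H0, pd$H0)
    if (config$svc) {
      lik$Hsvc2 <- rbind(lik$Hsvc2, pd$Hsvc2)
      lik$Hsvc3 <- rbind(lik$Hsvc3, pd$Hsvc3)
    }
    md$presence_table <- pr
  }
  md$lik <- lik
  md
}

#' Combine the base design with the trend scalings
#' @keywords internal
design_H <- function(md, b = c(1, 1)) {
  H <- md$lik$H0
  if (md$config$svc) H <- H + b[1] * md$lik$Hsvc2 + b[2] * md$lik$Hsvc3
  H
}

#' Assemble the latent predictor for every observation row
#'
#' eta is the exact sum of the active components; inactive components
#' contribute nothing. \code{state} is either a latent vector of layout
#' length or a named list of blocks (missing blocks default to zero).
#'
#' @param config A \code{fern_config} (must match \code{model_data}).
#' @param state Latent state (vector or named block list).
#' @param model_data Output of \code{build_model_data}.
#' @param b Trend scalings c(b2, b3) for species 2 and 3 (reference species
#'   fixed at 1).
#' @return Numeric eta vector, one element per likelihood row, with the row
#'   \code{type} as an attribute.
#' @export
assemble_predictor <- function(config, state, model_data, b = c(1, 1)) {
  lay <- model_data$layout
  if (is.list(state)) {
    x <- numeric(lay$n)
    for (nm in names(state)) {
      idx <- block_idx(lay, nm)
      if (!length(idx)) stop("state block '", nm, "' not active in this config")
      if (length(state[[nm]]) != length(idx))
        stop("state block '", nm, "' has length ", length(state[[nm]]),
             ", expected ", length(idx))
      x[idx] <- state[[nm]]
    }
  } else {
    x <- state
    if (length(x) != lay$n)
      stop("state vector has length ", length(x), ", expected ", lay$n)
  }
  eta <- as.vector(design_H(model_data, b) %*% x)
  attr(eta, "type") <- model_data$lik$type
  eta
}

#' Poisson / negative binomial log-likelihood of count observations
#'
#' log mu = log(area) + eta; Poisson for species 1 and 3, negative binomial
#' (mean mu, variance mu + mu^2/psi) for species 2. Missing records
#' contribute zero.
#'
#' @param observations Count data.frame (species, count, area_m2, missing).
#' @param eta Latent log-intensity per row.
#' @param psi Overdispersion (> 0) for the negative binomial species.
#' @return Scalar log-likelihood.
#' @export
loglik_counts <- function(observations, eta, psi = Inf) {
  keep <- !observations$missing
  y <- observations$count[keep]
  if (any(y < 0)) stop("negative counts")
  mu <- exp(log(observations$area_m2[keep]) + eta[keep])
  fam <- ifelse(observations$species[keep] == 2L, FAM_NEGBIN, FAM_POISSON)
  ll <- numeric(length(y))
  pois <- fam == FAM_POISSON | !is.finite(psi)
  ll[pois] <- stats::dpois(y[pois], mu[pois], log = TRUE)
  if (any(!pois))
    ll[!pois] <- stats::dnbinom(y[!pois], size = psi, mu = mu[!pois], log = TRUE)
  sum(ll)
}

#' Bernoulli (cloglog) log-likelihood of presence observations
#'
#' p = 1 - exp(-exp(eta_total)) where eta_total already includes the species
#' presence intercept and the road-distance bias term. Probabilities are
#' clamped away from 0 and 1 by a documented epsilon (1e-12) with a warning.
#'
#' @param observations data.frame with a binary \code{present} column.
#' @param eta_total Full presence-model predictor per row.
#' @return Scalar log-likelihood.
#' @export
loglik_presence <- function(observations, eta_total) {
  y <- observations$present
  if (!all(y %in% c(0, 1))) stop("presence indicator must be binary")
  lam <- exp(eta_total)
  p <- -expm1(-lam)
  eps <- 1e-12
  if (any(p < eps | p > 1 - eps)) {
    warning("presence probabilities clamped to [1e-12, 1-1e-12]")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  sum(y * log(p) + (1 - y) * log1p(-p))
}

#' Per-row observation log-likelihood, gradient and curvature in eta
#' @keywords internal
obs_loglik_terms <- function(y, family, offset, eta, psi) {
  # clamp to keep exp() finite: beyond +-35 the likelihood is numerically
  # flat anyway, and Inf curvatures would poison the sparse factorization
  lin <- pmin(pmax(eta + offset, -35), 35)
  ll <- g <- w <- numeric(length(y))
  i <- family == FAM_POISSON
  if (any(i)) {
    mu <- exp(lin[i])
    ll[i] <- y[i] * lin[i] - mu - lgamma(y[i] + 1)
    g[i] <- y[i] - mu
    w[i] <- mu
  }
  i <- family == FAM_NEGBIN
  if (any(i)) {
    mu <- exp(lin[i])
    ll[i] <- stats::dnbinom(y[i], size = psi, mu = mu, log = TRUE)
    g[i] <- y[i] - mu * (y[i] + psi) / (mu + psi)
    w[i] <- (y[i] + psi) * mu * psi / (mu + psi)^2
  }
  i <- family == FAM_BERNOULLI
  if (any(i)) {
    lam <- exp(lin[i])
    q <- exp(-lam)
    p <- pmin(pmax(-expm1(-lam), 1e-12), 1 - 1e-12)
    ll[i] <- ifelse(y[i] == 1, log(p), -lam)
    g[i] <- ifelse(y[i] == 1, lam * q / (1 - q), -lam)
    w[i] <- ifelse(y[i] == 1,
                   pmax(lam * q * (lam - (1 - q)) / (1 - q)^2, 1e-12), lam)
  }
  list(ll = ll, g = g, w = pmax(w, 1e-12))
}

#' Joint log-likelihood (posterior kernel) of a configured model
#'
#' Sum of the count log-likelihood, the presence log-likelihood (when fusion
#' is active), the latent GMRF and Gaussian-prior log-densities, and the PC
#' prior log-densities of the hyperparameters. The additive decomposition is
#' returned as an attribute.
#'
#' @param config A \code{fern_config}.
#' @param state Latent state (vector or block list; see
#'   \code{assemble_predictor}).
#' @param hypers Named list of hyperparameters (see \code{fit_isdm}); needs
#'   \code{psi} when the negative binomial is active, field parameters for the
#'   active random effects, and \code{b = c(b2, b3)} when the trend field is on.
#' @param data Model data from \code{build_model_data}.
#' @param priors Prior set (see \code{default_priors}).
#' @return Scalar with attribute \code{breakdown}.
#' @export
joint_loglik <- function(config, state, hypers, data, priors = default_priors()) {
  md <- data
  b <- if (config$svc) hypers$b else c(1, 1)
  lay <- md$layout
  x <- if (is.list(state)) {
    v <- numeric(lay$n)
    for (nm in names(state)) v[block_idx(lay, nm)] <- state[[nm]]
    v
  } else state
  eta <- as.vector(design_H(md, b) %*% x)
  psi <- if (!is.null(hypers$psi)) hypers$psi else Inf
  terms <- obs_loglik_terms(md$lik$y, md$lik$family, md$lik$offset, eta, psi)
  is_count <- md$lik$type == "count"
  ll_counts <- sum(terms$ll[is_count])
  ll_pres <- sum(terms$ll[!is_count])
  Q <- prior_precision(md, hypers)
  quad <- -0.5 * as.numeric(Matrix::crossprod(x, Q %*% x))
  ld <- 0.5 * logdet_spd(Q) - 0.5 * lay$n * log(2 * pi)
  lp_hyper <- hyper_log_prior(md, hypers, priors)
  total <- ll_counts + ll_pres + quad + ld + lp_hyper
  attr(total, "breakdown") <- c(counts = ll_counts, presence = ll_pres,
                                gmrf = quad + ld, hyper_prior = lp_hyper)
  total
}

#' Latent prior precision for a configuration and hyperparameter set
#' @keywords internal
prior_precision <- function(md, hypers) {
  cfg <- md$config; lay <- md$layout
  n_t <- length(md$years)
  fe_prec <- 1e-6  # Normal(0, 1000) on fixed effects / intercepts / gamma
  parts <- list()
  for (bl in lay$blocks) {
    nm <- bl$name
    parts[[nm]] <- switch(
      nm,
      beta = , intercept = , pres_intercept = , gamma_road =
        Matrix::Diagonal(bl$length, fe_prec),
      u = kronecker_st_precision(
        spde_precision(md$mesh, hypers$u$range, hypers$u$sigma),
        ar1_precision(n_t, hypers$u$rho)),
      delta1 = , delta2 = , delta3 = {
        j <- as.integer(substring(nm, 6))
        h <- if (!is.null(hypers$delta[[1]]) && is.list(hypers$delta[[1]]))
          hypers$delta[[j]] else hypers$delta
        kronecker_st_precision(spde_precision(md$mesh, h$range, h$sigma),
                               ar1_precision(n_t, h$rho))
      },
      spatial = spde_precision(md$mesh, hypers$spatial$range, hypers$spatial$sigma),
      omega = spde_precision(md$mesh, hypers$svc$range, hypers$svc$sigma),
      stop("unknown block ", nm))
  }
  Matrix::forceSymmetric(Matrix::bdiag(parts))
}

#' Hyperparameter log prior (PC priors + Gaussian scalings)
#' @keywords internal
hyper_log_prior <- function(md, hypers, priors) {
  cfg <- md$config
  lp <- 0
  if (cfg$shared_st)
    lp <- lp + pc_prior_logdensity(priors$st_field, c(hypers$u$range, hypers$u$sigma)) +
      pc_prior_logdensity(priors$ar1, hypers$u$rho)
  if (cfg$species_st) {
    hs <- if (!is.null(hypers$delta[[1]]) && is.list(hypers$delta[[1]]))
      hypers$delta else list(hypers$delta)
    for (h in hs)
      lp <- lp + pc_prior_logdensity(priors$st_field, c(h$range, h$sigma)) +
        pc_prior_logdensity(priors$ar1, h$rho)
  }
  if (cfg$spatial_spde)
    lp <- lp + pc_prior_logdensity(priors$st_field,
                                   c(hypers$spatial$range, hypers$spatial$sigma))
  if (cfg$svc) {
    lp <- lp + pc_prior_logdensity(priors$svc_field,
                                   c(hypers$svc$range, hypers$svc$sigma))
    lp <- lp + sum(vapply(hypers$b, function(bb)
      pc_prior_logdensity(priors$svc_scaling, bb), 0))
  }
  if (cfg$joint_structure && any(md$lik$family == FAM_NEGBIN))
    lp <- lp + pc_prior_logdensity(priors$overdispersion, hypers$psi)
  lp
}
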