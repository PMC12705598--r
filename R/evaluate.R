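# Model comparison and diagnostics: leave-population-out cross-validation
# log-score, WAIC, interval-coverage / amplitude / MAE report, and the
# buffer-radius spatial-redundancy diagnostic.

#' Posterior predictive count densities for a set of count rows
#'
#' Rao-Blackwellized: the count pmf is averaged over posterior samples of the
#' mean (and overdispersion). Returns the per-row predictive density.
#' @keywords internal
ppd_count_density <- function(md, fit_like, rows, sm) {
  yix <- match(rows$year, md$years)
  dz <- make_design(md, rows$species, rows$cell_id, yix, "count")
  E <- as.matrix(dz$H0 %*% sm$latent)
  if (md$config$svc) {
    ns <- ncol(sm$latent)
    E <- E + as.matrix(dz$Hsvc2 %*% sm$latent) %*% diag(sm$b[1, ], ns) +
      as.matrix(dz$Hsvc3 %*% sm$latent) %*% diag(sm$b[2, ], ns)
  }
  mu <- pmin(exp(E + log(rows$area_m2)), 1e8)  # overflow guard on wild draws
  dens <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    if (md$config$joint_structure && rows$species[i] == 2L) {
      dens[i] <- mean(stats::dnbinom(rows$count[i], size = sm$psi, mu = mu[i, ]))
    } else {
      dens[i] <- mean(stats::dpois(rows$count[i], mu[i, ]))
    }
  }
  dens
}

#' Refit only the latent field of a fitted model on new model data
#' @keywords internal
refit_latent <- function(fit, md) {
  h <- fit$hyper_mode
  Q <- prior_precision(md, h)
  H <- design_H(md, if (fit$config$svc) h$b else c(1, 1))
  nl <- newton_latent(numeric(md$layout$n), H, Q, md$lik$y, md$lik$family,
                      md$lik$offset, h$psi %||% Inf,
                      fit$options$inner_tol, fit$options$inner_maxit)
  out <- fit
  out$model_data <- md
  out$x_mode <- nl$x
  out$chol_post <- nl$chol
  out$loglik <- nl$loglik
  out$converged <- nl$converged
  out
}

#' Leave-population-out cross-validation log-score
#'
#' For each population, all of its count observations are removed from the
#' training set, the model is refit, and the posterior predictive density of
#' each held-out (non-missing) observation is evaluated by posterior
#' sampling. The log-score is the mean of the log predictive densities over
#' all held-out observations.
#'
#' @param config A \code{fern_config}.
#' @param data List with \code{domain}, \code{mesh}, \code{covariates},
#'   \code{counts}, optional \code{presences}, \code{covariate_names},
#'   \code{presence_mode}.
#' @param priors Prior set.
#' @param options \code{fit_options}; with
#'   \code{freeze_hyperparameters = TRUE} the hyperparameters are optimized
#'   once on the full data and only the latent field is refit per fold.
#' @param n_samples Posterior samples per fold for the predictive densities.
#' @param seed Integer seed.
#' @param freeze_hyperparameters See above (default FALSE: re-optimize per
#'   fold, warm-started at the full-data hyperparameter mode).
#' @param fold_outer_maxit Outer-optimizer budget for the warm-started fold
#'   refits (default: same as \code{options$outer_maxit}).
#' @return List: \code{log_score}, \code{per_obs} (data.frame with species,
#'   population, cell_id, year, count, ppd_density), \code{n}.
#' @export
lpocv_logscore <- function(config, data, priors = default_priors(),
                           options = fit_options(), n_samples = 100L, seed = 1L,
                           freeze_hyperparameters = FALSE,
                           fold_outer_maxit = NULL) {
  counts <- data$counts
  # sorted fold order: the schedule (and fold seeds) must not depend on row order
  pops <- sort(unique(counts$population))
  if (length(pops) < 2L) stop("leave-population-out needs at least 2 populations")
  full_opts <- options
  full_opts$compute_hessian <- FALSE  # folds sample at their own modes
  full_fit <- fit_isdm(config, data, priors, full_opts, seed = seed)
  fold_opts <- full_opts
  fold_opts$theta_start <- unname(full_fit$theta_mode)
  if (!is.null(fold_outer_maxit)) fold_opts$outer_maxit <- fold_outer_maxit
  per <- list()
  for (k in seq_along(pops)) {
    g <- pops[k]
    held <- counts[counts$population == g & !counts$missing, , drop = FALSE]
    if (nrow(held) == 0L) next
    train <- counts[counts$population != g, , drop = FALSE]
    dk <- data; dk$counts <- train
    if (freeze_hyperparameters) {
      mdk <- build_model_data(config, dk$domain, dk$mesh, dk$covariates,
                              dk$counts, dk$presences,
                              covariate_names = dk$covariate_names %||% character(0),
                              presence_mode = dk$presence_mode %||% "all_cells")
      fk <- refit_latent(full_fit, mdk)
    } else {
      fk <- fit_isdm(config, dk, priors, fold_opts, seed = seed + k)
    }
    # frozen mode conditions the fold PPDs on the full-data hyperparameter
    # mode; the default (re-optimized) mode propagates fold hyperparameter
    # uncertainty through the sampled draws
    sm <- sample_posterior(fk, n_samples, seed = seed + 1000L + k,
                           n_theta = if (freeze_hyperparameters) 1L else 10L)
    dens <- ppd_count_density(fk$model_data, fk, held, sm)
    per[[length(per) + 1L]] <- data.frame(
      species = held$species, population = held$population,
      cell_id = held$cell_id, year = held$year, count = held$count,
      ppd_density = dens)
  }
  per <- do.call(rbind, per)
  list(log_score = mean(log(pmax(per$ppd_density, 1e-300))),
       per_obs = per, n = nrow(per))
}

#' Watanabe-Akaike information criterion of a fitted model
#'
#' WAIC = -2 (lppd - p_waic): lppd sums the log of the posterior-mean
#' pointwise likelihood; the effective number of parameters p_waic sums the
#' posterior variance of the pointwise log-likelihood. Computed over all
#' likelihood rows (counts, and presences when fused).
#'
#' @param result A \code{fern_fit}.
#' @param n_samples Posterior samples (>= 2).
#' @param seed Integer seed.
#' @return List: \code{waic}, \code{p_waic}, \code{lppd}.
#' @export
waic <- function(result, n_samples = 400L, seed = 1L) {
  if (n_samples < 2L) stop("WAIC needs at least 2 posterior samples")
  md <- result$model_data
  sm <- sample_posterior(result, n_samples, seed = seed)
  ll <- matrix(0, length(md$lik$y), n_samples)
  for (s in seq_len(n_samples)) {
    H <- design_H(md, sm$b[, s])
    eta <- as.vector(H %*% sm$latent[, s])
    ll[, s] <- obs_loglik_terms(md$lik$y, md$lik$family, md$lik$offset, eta,
                                sm$psi[s])$ll
  }
  m <- apply(ll, 1, max)
  lppd <- sum(m + log(rowMeans(exp(ll - m))))
  p_waic <- sum(apply(ll, 1, stats::var))
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd)
}

#' Coverage, interval-amplitude and error report for count predictions
#'
#' For every count record (observed and missing), posterior intervals of the
#' expected count mu = area x lambda (intensity intervals, "I") and of
#' simulated predictive counts ("PPD") are computed from posterior samples.
#' Coverage percentages are evaluated on observed records; amplitude
#' statistics are reported for observed records and separately for
#' missing-year records; MAE compares observed counts with the posterior
#' mean of mu.
#'
#' @param result A \code{fern_fit}.
#' @param levels Credible levels for the intensity intervals (default 0.75,
#'   0.95).
#' @param n_samples Posterior samples.
#' @param seed Integer seed.
#' @return List with \code{per_species} (data.frame of metrics by species)
#'   and \code{overall}.
#' @export
coverage_report <- function(result, levels = c(0.75, 0.95), n_samples = 400L,
                            seed = 1L) {
  md <- result$model_data
  counts <- md$counts
  sm <- sample_posterior(result, n_samples, seed = seed)
  yix <- match(counts$year, md$years)
  dz <- make_design(md, counts$species, counts$cell_id, yix, "count")
  E <- as.matrix(dz$H0 %*% sm$latent)
  if (md$config$svc) {
    E <- E + as.matrix(dz$Hsvc2 %*% sm$latent) %*% diag(sm$b[1, ], n_samples) +
      as.matrix(dz$Hsvc3 %*% sm$latent) %*% diag(sm$b[2, ], n_samples)
  }
  mu <- pmin(exp(E + log(counts$area_m2)), 1e8)  # overflow guard on wild draws
  set.seed(seed + 1L)
  ystar <- matrix(0L, nrow(counts), n_samples)
  nb <- md$config$joint_structure & counts$species == 2L
  for (s in seq_len(n_samples)) {
    ystar[!nb, s] <- stats::rpois(sum(!nb), mu[!nb, s])
    if (any(nb)) ystar[nb, s] <- stats::rnbinom(sum(nb), size = sm$psi[s],
                                                mu = mu[nb, s])
  }
  obs <- !counts$missing
  metrics_for <- function(sel) {
    res <- list()
    mu_mean <- rowMeans(mu[sel, , drop = FALSE])
    y <- counts$count[sel]
    ok <- obs[sel]
    for (lv in levels) {
      a <- (1 - lv) / 2
      lo <- apply(mu[sel, , drop = FALSE], 1, stats::quantile, probs = a)
      hi <- apply(mu[sel, , drop = FALSE], 1, stats::quantile, probs = 1 - a)
      res[[sprintf("pPCPI_I_%d", round(lv * 100))]] <-
        if (any(ok)) 100 * mean(y[ok] >= lo[ok] & y[ok] <= hi[ok]) else NA_real_
      res[[sprintf("amp_I_%d_mean", round(lv * 100))]] <- mean(hi[ok] - lo[ok])
      res[[sprintf("amp_I_%d_sd", round(lv * 100))]] <- stats::sd(hi[ok] - lo[ok])
      res[[sprintf("amp_I_%d_mean_NA", round(lv * 100))]] <-
        if (any(!ok)) mean(hi[!ok] - lo[!ok]) else NA_real_
      res[[sprintf("amp_I_%d_sd_NA", round(lv * 100))]] <-
        if (sum(!ok) > 1) stats::sd(hi[!ok] - lo[!ok]) else NA_real_
    }
    lo <- apply(ystar[sel, , drop = FALSE], 1, stats::quantile, probs = 0.025)
    hi <- apply(ystar[sel, , drop = FALSE], 1, stats::quantile, probs = 0.975)
    res$pPCPI_PPD_95 <- if (any(ok)) 100 * mean(y[ok] >= lo[ok] & y[ok] <= hi[ok]) else NA_real_
    res$amp_PPD_95_mean <- mean(hi[ok] - lo[ok])
    res$amp_PPD_95_mean_NA <- if (any(!ok)) mean(hi[!ok] - lo[!ok]) else NA_real_
    res$MAE <- if (any(ok)) mean(abs(y[ok] - mu_mean[ok])) else NA_real_
    as.data.frame(res)
  }
  per_species <- do.call(rbind, lapply(1:3, function(j) {
    sel <- counts$species == j
    if (!any(sel)) return(NULL)
    cbind(species = j, metrics_for(sel))
  }))
  list(per_species = per_species, overall = metrics_for(rep(TRUE, nrow(counts))))
}

#' Spatial redundancy between two point sets
#'
#' Percentage of \code{points_b} lying within \code{radius_m} of any point of
#' \code{points_a}; with \code{symmetric = TRUE} the mean of both directions.
#'
#' @param points_a,points_b Two-column coordinate matrices (same projection).
#' @param radius_m Buffer radius in meters (> 0).
#' @param symmetric Average both directions.
#' @return Percentage in [0, 100].
#' @export
spatial_redundancy <- function(points_a, points_b, radius_m, symmetric = FALSE) {
  points_a <- rbind(points_a); points_b <- rbind(points_b)
  if (nrow(points_a) == 0L || nrow(points_b) == 0L) stop("empty point set")
  if (radius_m <= 0) stop("radius must be positive")
  near <- function(p, q) {
    d2 <- outer(p[, 1], q[, 1], "-")^2 + outer(p[, 2], q[, 2], "-")^2
    100 * mean(apply(d2, 1, min) <= radius_m^2)
  }
  if (symmetric) (near(points_b, points_a) + near(points_a, points_b)) / 2
  else near(points_b, points_a)
}

#' Compare model configurations on one dataset
#'
#' Fits each configuration, computes WAIC and the LPOCV log-score, and emits
#' a comparison table (model, likelihood at the mode, log-score, WAIC).
#'
#' @param configs List of \code{fern_config}s (or model-id strings).
#' @param data Data list as for \code{fit_isdm}.
#' @param priors,options,n_samples,seed,freeze_hyperparameters Passed through.
#' @return data.frame, one row per model.
#' @export
compare_models <- function(configs, data, priors = default_priors(),
                           options = fit_options(), n_samples = 100L,
                           seed = 1L, freeze_hyperparameters = TRUE) {
  all_cfg <- NULL
  rows <- lapply(configs, function(cf) {
    if (is.character(cf)) {
      if (is.null(all_cfg)) all_cfg <<- make_configs()
      cf <- all_cfg[[cf]]
    }
    fit <- fit_isdm(cf, data, priors, options, seed = seed)
    w <- waic(fit, n_samples = max(2L, n_samples), seed = seed)
    ls <- lpocv_logscore(cf, data, priors, options, n_samples = n_samples,
                         seed = seed,
                         freeze_hyperparameters = freeze_hyperparameters)
    data.frame(model = cf$model %||% "(ad hoc)", loglik = fit$loglik,
               log_score = ls$log_score, waic = w$waic)
  })
  do.call(rbind, rows)
}
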