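# Laplace-approximation inference. Inner loop: Newton optimization of the
# latent Gaussian field given hyperparameters, with sparse Cholesky solves and
# step-halving line search. Outer loop: Nelder-Mead on the Laplace-approximate
# log marginal posterior of the (transformed) hyperparameters. Hyperparameter
# uncertainty is summarized by a Gaussian approximation at the mode with a
# finite-difference Hessian; posterior sampling propagates it.

#' Fitting options
#'
#' @param inner_tol Gradient infinity-norm tolerance of the latent Newton
#'   loop.
#' @param inner_maxit Maximum Newton iterations.
#' @param outer_maxit Maximum Nelder-Mead evaluations of the Laplace
#'   objective.
#' @param outer_reltol Relative convergence tolerance of the outer optimizer.
#' @param tie_species_hypers Share one (range, sd, rho) triple across the
#'   species-specific spatio-temporal fields (keeps the outer search
#'   low-dimensional; the untied mode estimates one triple per species).
#' @param compute_hessian Compute the finite-difference Hessian of the
#'   hyperparameter posterior at the mode.
#' @param hessian_step Finite-difference step on the transformed scale.
#' @param theta_start Optional transformed hyperparameter vector to start
#'   the outer optimization from (default: prior medians); used e.g. to
#'   warm-start cross-validation fold refits at the full-data mode.
#' @return List of options.
#' @export
fit_options <- function(inner_tol = 1e-6, inner_maxit = 100L, outer_maxit = 400L,
                        outer_reltol = 1e-7, tie_species_hypers = FALSE,
                        compute_hessian = TRUE, hessian_step = 0.05,
                        theta_start = NULL) {
  list(inner_tol = inner_tol, inner_maxit = inner_maxit,
       outer_maxit = outer_maxit, outer_reltol = outer_reltol,
       tie_species_hypers = tie_species_hypers,
       compute_hessian = compute_hessian, hessian_step = hessian_step,
       theta_start = theta_start)
}

#' Hyperparameter layout for a configuration
#' @keywords internal
hyper_layout <- function(config, tie_species, any_negbin) {
  ent <- list()
  add <- function(name, transform) ent[[length(ent) + 1L]] <<-
    list(name = name, transform = transform)
  if (config$shared_st) { add("u.range", "log"); add("u.sigma", "log"); add("u.rho", "rho") }
  if (config$species_st) {
    if (tie_species) { add("d.range", "log"); add("d.sigma", "log"); add("d.rho", "rho") }
    else for (j in 1:3) { add(sprintf("d%d.range", j), "log")
      add(sprintf("d%d.sigma", j), "log"); add(sprintf("d%d.rho", j), "rho") }
  }
  if (config$spatial_spde) { add("s.range", "log"); add("s.sigma", "log") }
  if (config$svc) { add("w.range", "log"); add("w.sigma", "log")
    add("b2", "id"); add("b3", "id") }
  if (config$joint_structure && any_negbin) add("psi", "log")
  ent
}

#' @keywords internal
theta_to_hypers <- function(theta, hl, config, tie_species) {
  v <- numeric(length(hl)); names(v) <- vapply(hl, `[[`, "", "name")
  for (k in seq_along(hl)) {
    v[k] <- switch(hl[[k]]$transform,
                   log = exp(theta[k]),
                   rho = tanh(theta[k] / 2),
                   id = theta[k])
  }
  h <- list()
  if (config$shared_st)
    h$u <- list(range = v[["u.range"]], sigma = v[["u.sigma"]], rho = v[["u.rho"]])
  if (config$species_st) {
    if (tie_species)
      h$delta <- list(range = v[["d.range"]], sigma = v[["d.sigma"]], rho = v[["d.rho"]])
    else
      h$delta <- lapply(1:3, function(j)
        list(range = v[[sprintf("d%d.range", j)]],
             sigma = v[[sprintf("d%d.sigma", j)]],
             rho = v[[sprintf("d%d.rho", j)]]))
  }
  if (config$spatial_spde)
    h$spatial <- list(range = v[["s.range"]], sigma = v[["s.sigma"]])
  if (config$svc) {
    h$svc <- list(range = v[["w.range"]], sigma = v[["w.sigma"]])
    h$b <- c(v[["b2"]], v[["b3"]])
  }
  if ("psi" %in% names(v)) h$psi <- v[["psi"]]
  h
}

#' Log-Jacobian of the transform theta -> hypers
#' @keywords internal
theta_log_jacobian <- function(theta, hl) {
  lj <- 0
  for (k in seq_along(hl)) {
    lj <- lj + switch(hl[[k]]$transform,
                      log = theta[k],
                      rho = log((1 - tanh(theta[k] / 2)^2) / 2),
                      id = 0)
  }
  lj
}

#' Initial transformed hyperparameters at prior medians
#' @keywords internal
theta_init <- function(hl, priors) {
  med_range <- function(sp) sp$lambda_range / log(2)
  med_sigma <- function(sp) log(2) / sp$lambda_sigma
  med_rho <- function(sp) {
    f <- function(d) (1 - exp(-sp$lambda * d)) / (1 - exp(-sp$lambda * sqrt(2))) - 0.5
    d <- stats::uniroot(f, c(1e-9, sqrt(2) - 1e-9))$root
    1 - d^2
  }
  th <- numeric(length(hl))
  for (k in seq_along(hl)) {
    nm <- hl[[k]]$name
    th[k] <- if (grepl("\\.range$", nm)) {
      sp <- if (startsWith(nm, "w")) priors$svc_field else priors$st_field
      log(med_range(sp))
    } else if (grepl("\\.sigma$", nm)) {
      sp <- if (startsWith(nm, "w")) priors$svc_field else priors$st_field
      log(med_sigma(sp))
    } else if (grepl("\\.rho$", nm)) {
      r <- med_rho(priors$ar1); log((1 + r) / (1 - r))
    } else if (nm == "psi") {
      log(priors$overdispersion$lambda / log(2))  # median of 1/psi inverted
    } else 1  # trend scalings start at the reference scaling
  }
  th
}

#' Newton maximization of the latent field given hyperparameters
#' @keywords internal
newton_latent <- function(x0, H, Q, y, family, offset, psi, tol, maxit) {
  x <- x0
  eta <- as.vector(H %*% x)
  tr <- obs_loglik_terms(y, family, offset, eta, psi)
  obj <- sum(tr$ll) - 0.5 * as.numeric(Matrix::crossprod(x, Q %*% x))
  conv <- FALSE
  ch <- NULL
  for (it in seq_len(maxit)) {
    grad <- as.vector(Matrix::crossprod(H, tr$g)) - as.vector(Q %*% x)
    if (max(abs(grad)) < tol) { conv <- TRUE; break }
    P <- Matrix::forceSymmetric(Q + Matrix::crossprod(H, H * tr$w))
    ch <- tryCatch(Matrix::Cholesky(P, LDL = FALSE, perm = TRUE),
                   error = function(e) NULL)
    if (is.null(ch)) stop("singular information in latent Newton step")
    step <- as.vector(Matrix::solve(ch, grad, system = "A"))
    s <- 1
    repeat {
      xn <- x + s * step
      etan <- as.vector(H %*% xn)
      trn <- obs_loglik_terms(y, family, offset, etan, psi)
      objn <- sum(trn$ll) - 0.5 * as.numeric(Matrix::crossprod(xn, Q %*% xn))
      if (is.finite(objn) && objn >= obj - 1e-10) break
      s <- s / 2
      if (s < 1e-8) { xn <- x; etan <- eta; trn <- tr; objn <- obj; break }
    }
    moved <- objn - obj
    x <- xn; eta <- etan; tr <- trn; obj <- objn
    if (moved < 1e-10 && it > 1L) { conv <- TRUE; break }
  }
  P <- Matrix::forceSymmetric(Q + Matrix::crossprod(H, H * tr$w))
  ch <- Matrix::Cholesky(P, LDL = FALSE, perm = TRUE)
  list(x = x, eta = eta, loglik = sum(tr$ll), obj = obj, chol = ch,
       logdet_post = 2 * Matrix::determinant(ch, logarithm = TRUE,
                                             sqrt = TRUE)$modulus[[1]],
       converged = conv, iterations = it)
}

#' Fit a configured integrated distribution model
#'
#' @param config A \code{fern_config}.
#' @param data Either model data from \code{build_model_data} or a list with
#'   \code{domain}, \code{mesh}, \code{covariates}, \code{counts}, optional
#'   \code{presences}, \code{covariate_names}, \code{presence_mode}.
#' @param priors Prior set (see \code{default_priors}).
#' @param options See \code{fit_options}.
#' @param seed Seed recorded with the result (inference itself is
#'   deterministic).
#' @return Object of class \code{fern_fit}: latent mode \code{x_mode}, sparse
#'   posterior precision Cholesky, hyperparameter mode/covariance (transformed
#'   scale), optimizer trace, model data, convergence flag.
#' @export
fit_isdm <- function(config, data, priors = default_priors(),
                     options = fit_options(), seed = 1L) {
  md <- if (!is.null(data$lik)) data else
    build_model_data(config, data$domain, data$mesh, data$covariates,
                     data$counts, data$presences,
                     covariate_names = data$covariate_names %||% character(0),
                     presence_mode = data$presence_mode %||% "all_cells")
  hl <- hyper_layout(config, options$tie_species_hypers,
                     any(md$lik$family == FAM_NEGBIN))
  lik <- md$lik
  trace <- list()
  warm <- new.env(parent = emptyenv())
  warm$x <- numeric(md$layout$n)
  eval_theta <- function(theta) {
    h <- theta_to_hypers(theta, hl, config, options$tie_species_hypers)
    Q <- prior_precision(md, h)
    H <- design_H(md, if (config$svc) h$b else c(1, 1))
    nl <- newton_latent(warm$x, H, Q, lik$y, lik$family, lik$offset,
                        h$psi %||% Inf, options$inner_tol, options$inner_maxit)
    warm$x <- nl$x
    lp <- nl$loglik -
      0.5 * as.numeric(Matrix::crossprod(nl$x, Q %*% nl$x)) +
      0.5 * logdet_spd(Q) - 0.5 * nl$logdet_post +
      hyper_log_prior(md, h, priors) + theta_log_jacobian(theta, hl)
    attr(lp, "newton") <- nl
    lp
  }
  if (length(hl) == 0L) {
    Q <- prior_precision(md, list())
    H <- design_H(md)
    nl <- newton_latent(numeric(md$layout$n), H, Q, lik$y, lik$family,
                        lik$offset, Inf, options$inner_tol, options$inner_maxit)
    res <- list(theta_mode = numeric(0), theta_vcov = matrix(0, 0, 0),
                hyper_mode = list(), x_mode = nl$x, chol_post = nl$chol,
                loglik = nl$loglik, lp = nl$obj, converged = nl$converged,
                trace = data.frame())
  } else {
    th0 <- if (!is.null(options$theta_start)) options$theta_start else
      theta_init(hl, priors)
    negobj <- function(theta) {
      lp <- tryCatch(as.numeric(eval_theta(theta)), error = function(e) -Inf)
      trace[[length(trace) + 1L]] <<- c(theta, lp = lp)
      if (!is.finite(lp)) 1e10 else -lp
    }
    opt <- stats::optim(th0, negobj, method = "Nelder-Mead",
                        control = list(maxit = options$outer_maxit,
                                       reltol = options$outer_reltol))
    theta_hat <- opt$par
    lp_hat <- eval_theta(theta_hat)
    nl <- attr(lp_hat, "newton")
    vcov <- matrix(NA_real_, length(hl), length(hl))
    if (options$compute_hessian) {
      f <- function(t) {
        v <- tryCatch(as.numeric(eval_theta(t)), error = function(e) NA_real_)
        if (is.finite(v)) v else NA_real_
      }
      Hh <- fd_hessian(f, theta_hat, options$hessian_step, as.numeric(lp_hat))
      # curvature eigenvalues clamped: directions the finite-difference
      # Hessian resolves poorly (flat or slightly negative) get at most
      # sd = 2 on the transformed scale instead of a degenerate variance
      ev <- eigen(-(Hh + t(Hh)) / 2, symmetric = TRUE)
      val <- pmin(pmax(ev$values, 0.25), 1e8)
      vcov <- ev$vectors %*% diag(1 / val, length(val)) %*% t(ev$vectors)
    }
    res <- list(theta_mode = stats::setNames(theta_hat, vapply(hl, `[[`, "", "name")),
                theta_vcov = vcov,
                hyper_mode = theta_to_hypers(theta_hat, hl, config,
                                             options$tie_species_hypers),
                x_mode = nl$x, chol_post = nl$chol, loglik = nl$loglik,
                lp = as.numeric(lp_hat),
                converged = opt$convergence == 0 && nl$converged,
                trace = if (length(trace)) as.data.frame(do.call(rbind, trace))
                        else data.frame())
  }
  res$config <- config
  res$model_data <- md
  res$hyper_layout <- hl
  res$options <- options
  res$priors <- priors
  res$seed <- seed
  class(res) <- "fern_fit"
  res
}

#' Laplace-approximate log marginal posterior at given hyperparameters
#'
#' Recomputes the outer objective of \code{fit_isdm} (latent Newton
#' maximization plus the Laplace determinant correction, hyperparameter
#' priors and transform Jacobian) at an arbitrary transformed hyperparameter
#' vector. Useful for probing local optimality of a fitted mode.
#'
#' @param fit A \code{fern_fit} with at least one hyperparameter.
#' @param theta Transformed hyperparameter vector (same layout/order as
#'   \code{fit$theta_mode}).
#' @return Scalar log posterior (up to a constant).
#' @export
laplace_lp <- function(fit, theta) {
  if (!length(fit$theta_mode)) stop("model has no hyperparameters")
  md <- fit$model_data; cfg <- fit$config
  h <- theta_to_hypers(theta, fit$hyper_layout, cfg,
                       fit$options$tie_species_hypers)
  Q <- prior_precision(md, h)
  H <- design_H(md, if (cfg$svc) h$b else c(1, 1))
  nl <- newton_latent(fit$x_mode, H, Q, md$lik$y, md$lik$family, md$lik$offset,
                      h$psi %||% Inf, fit$options$inner_tol,
                      fit$options$inner_maxit)
  nl$loglik - 0.5 * as.numeric(Matrix::crossprod(nl$x, Q %*% nl$x)) +
    0.5 * logdet_spd(Q) - 0.5 * nl$logdet_post +
    hyper_log_prior(md, h, fit$priors) + theta_log_jacobian(theta, fit$hyper_layout)
}

#' Finite-difference Hessian: central on the diagonal, forward cross terms
#' @keywords internal
fd_hessian <- function(f, x, h, f0 = f(x)) {
  n <- length(x)
  H <- matrix(NA_real_, n, n)
  fp <- fm <- numeric(n)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- h
    fp[i] <- f(x + e); fm[i] <- f(x - e)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ei <- numeric(n); ei[i] <- h; ej <- numeric(n); ej[j] <- h
    H[i, j] <- H[j, i] <- (f(x + ei + ej) - fp[i] - fp[j] + f0) / h^2
  }
  H[!is.finite(H)] <- 0
  (H + t(H)) / 2
}

#' @export
print.fern_fit <- function(x, ...) {
  cat(sprintf("fern_fit %s: %d latent, %d hyperparameters, lp = %.3f, %s\n",
              x$config$model %||% "(ad hoc)", x$model_data$layout$n,
              length(x$theta_mode), x$lp,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Posterior intervals for the hyperparameters
#'
#' Gaussian approximation on the transformed scale, back-transformed to the
#' natural scale (ranges and sds are log-normal, correlations tanh-normal).
#'
#' @param fit A \code{fern_fit}.
#' @param level Credible level (default 0.95).
#' @return data.frame: name, mode, lower, upper.
#' @export
hyper_intervals <- function(fit, level = 0.95) {
  if (!length(fit$theta_mode)) return(data.frame())
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(diag(fit$theta_vcov), 0))
  back <- function(t, tr) switch(tr, log = exp(t), rho = tanh(t / 2), id = t)
  trs <- vapply(fit$hyper_layout, `[[`, "", "transform")
  data.frame(name = names(fit$theta_mode),
             mode = mapply(back, fit$theta_mode, trs),
             lower = mapply(back, fit$theta_mode - z * se, trs),
             upper = mapply(back, fit$theta_mode + z * se, trs),
             row.names = NULL)
}

#' Draw samples from the approximate posterior
#'
#' Hyperparameters are drawn from the Gaussian approximation at the mode;
#' for each hyperparameter draw the latent conditional mode and Gaussian
#' approximation are refreshed (warm-started Newton) and latent vectors are
#' drawn from that Gaussian via the sparse Cholesky factor.
#'
#' @param result A \code{fern_fit}.
#' @param n_samples Number of latent draws (> 0).
#' @param seed Integer seed.
#' @param n_theta Number of distinct hyperparameter draws the latent draws
#'   are spread over (default 10; forced to 1 when there are no
#'   hyperparameters or no Hessian).
#' @return List: \code{latent} (matrix n_latent x n_samples), \code{theta}
#'   (matrix n_hyper x n_samples, transformed scale), \code{b} (2 x n_samples
#'   trend scalings actually applied).
#' @export
sample_posterior <- function(result, n_samples, seed = 1L, n_theta = 10L) {
  if (n_samples <= 0) stop("n_samples must be positive")
  set.seed(seed)
  md <- result$model_data; cfg <- result$config
  nh <- length(result$theta_mode)
  use_theta <- nh > 0 && all(is.finite(result$theta_vcov)) && nh > 0 &&
    result$options$compute_hessian
  n_theta <- if (use_theta) max(1L, min(n_theta, n_samples)) else 1L
  sizes <- rep(n_samples %/% n_theta, n_theta)
  if (n_samples %% n_theta > 0) sizes[seq_len(n_samples %% n_theta)] <-
    sizes[seq_len(n_samples %% n_theta)] + 1L
  Ls <- if (use_theta) t(chol(result$theta_vcov + 1e-10 * diag(nh))) else NULL
  lat <- matrix(0, md$layout$n, n_samples)
  thetas <- matrix(0, nh, n_samples)
  bs <- matrix(1, 2, n_samples)
  psis <- rep(Inf, n_samples)
  col <- 0L
  for (g in seq_len(n_theta)) {
    theta_g <- if (use_theta && g > 1L)
      as.vector(result$theta_mode + Ls %*% stats::rnorm(nh)) else
        as.vector(result$theta_mode)
    h <- theta_to_hypers(theta_g, result$hyper_layout, cfg,
                         result$options$tie_species_hypers)
    if (nh > 0) {
      nl <- tryCatch({
        Q <- prior_precision(md, h)
        H <- design_H(md, if (cfg$svc) h$b else c(1, 1))
        newton_latent(result$x_mode, H, Q, md$lik$y, md$lik$family,
                      md$lik$offset, h$psi %||% Inf, 1e-5, 25L)
      }, error = function(e) NULL)
      if (is.null(nl)) { # degenerate draw: fall back to the mode's Gaussian
        mode_g <- result$x_mode; ch <- result$chol_post
        h <- result$hyper_mode
      } else { mode_g <- nl$x; ch <- nl$chol }
    } else { mode_g <- result$x_mode; ch <- result$chol_post }
    z <- matrix(stats::rnorm(md$layout$n * sizes[g]), md$layout$n, sizes[g])
    v <- Matrix::solve(ch, z, system = "Lt")
    xs <- as.matrix(Matrix::solve(ch, v, system = "Pt")) + mode_g
    idx <- col + seq_len(sizes[g])
    lat[, idx] <- xs
    if (nh > 0) thetas[, idx] <- theta_g
    if (cfg$svc) bs[, idx] <- h$b
    if (!is.null(h$psi)) psis[idx] <- h$psi
    col <- col + sizes[g]
  }
  rownames(thetas) <- names(result$theta_mode)
  list(latent = lat, theta = thetas, b = bs, psi = psis)
}
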