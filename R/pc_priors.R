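# Penalized-complexity (PC) priors. Each prior shrinks toward a base model and
# is calibrated by tail-probability statements:
#   - Matern range r (2D):  P(r < r0) = a_r, density  lam r^-2 exp(-lam/r),
#     lam = -r0 log(a_r); base model is an infinitely smooth field (r -> Inf).
#   - Marginal sd s:        P(s > s0) = a_s, exponential with rate -log(a_s)/s0;
#     base model is no field (s = 0).
#   - AR(1) correlation:    base model rho = 1 (no temporal change); distance
#     d = sqrt(1 - rho) has a truncated-exponential density on (0, sqrt(2)),
#     rate solved from P(rho > u0) = a.
#   - NegBin overdispersion: base model Poisson (psi -> Inf); exponential PC
#     prior on the distance scale s = 1/psi with P(1/psi > s0) = a.

#' Construct a PC prior specification
#'
#' @param kind One of \code{"matern_range_sd"}, \code{"ar1_correlation"},
#'   \code{"overdispersion"}, \code{"gaussian_fixed"}.
#' @param ... Calibration pairs by kind:
#'   \code{matern_range_sd}: \code{range0}, \code{p_range_below} (P(range < range0)),
#'   \code{sigma0}, \code{p_sigma_above} (P(sd > sigma0)).
#'   \code{ar1_correlation}: \code{rho0}, \code{p_above} (P(rho > rho0)).
#'   \code{overdispersion}: \code{inv_psi0}, \code{p_above} (P(1/psi > inv_psi0)).
#'   \code{gaussian_fixed}: \code{mean}, \code{sd}.
#' @return Object of class \code{pc_prior}.
#' @export
pc_prior <- function(kind = c("matern_range_sd", "ar1_correlation",
                              "overdispersion", "gaussian_fixed"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  spec <- switch(kind,
    matern_range_sd = {
      stopifnot(p$range0 > 0, p$p_range_below > 0, p$p_range_below < 1,
                p$sigma0 > 0, p$p_sigma_above > 0, p$p_sigma_above < 1)
      list(kind = kind, range0 = p$range0, p_range_below = p$p_range_below,
           sigma0 = p$sigma0, p_sigma_above = p$p_sigma_above,
           lambda_range = -p$range0 * log(p$p_range_below),
           lambda_sigma = -log(p$p_sigma_above) / p$sigma0)
    },
    ar1_correlation = {
      stopifnot(abs(p$rho0) < 1, p$p_above > 0, p$p_above < 1)
      d0 <- sqrt(1 - p$rho0)
      f <- function(lam) (1 - exp(-lam * d0)) / (1 - exp(-lam * sqrt(2))) - p$p_above
      lam <- stats::uniroot(f, c(1e-8, 1e3), tol = 1e-12)$root
      list(kind = kind, rho0 = p$rho0, p_above = p$p_above, lambda = lam)
    },
    overdispersion = {
      inv_psi0 <- if (is.null(p$inv_psi0)) 5 else p$inv_psi0
      p_above <- if (is.null(p$p_above)) 0.1 else p$p_above
      stopifnot(inv_psi0 > 0, p_above > 0, p_above < 1)
      list(kind = kind, inv_psi0 = inv_psi0, p_above = p_above,
           lambda = -log(p_above) / inv_psi0)
    },
    gaussian_fixed = {
      stopifnot(p$sd > 0)
      list(kind = kind, mean = if (is.null(p$mean)) 0 else p$mean, sd = p$sd)
    })
  structure(spec, class = "pc_prior")
}

#' Log density of a PC prior
#'
#' For \code{matern_range_sd}, \code{value} is \code{c(range, sigma)} and the
#' joint density is the product of the range and sd marginals. Values outside
#' the support return \code{-Inf}.
#'
#' @param spec A \code{pc_prior}.
#' @param value Parameter value (vector of length 2 for the joint Matern prior).
#' @return Log density (scalar).
#' @export
pc_prior_logdensity <- function(spec, value) {
  stopifnot(inherits(spec, "pc_prior"))
  switch(spec$kind,
    matern_range_sd = {
      r <- value[1]; s <- value[2]
      if (r <= 0 || s < 0) return(-Inf)
      lr <- log(spec$lambda_range) - 2 * log(r) - spec$lambda_range / r
      ls <- log(spec$lambda_sigma) - spec$lambda_sigma * s
      lr + ls
    },
    ar1_correlation = {
      rho <- value[1]
      if (rho <= -1 || rho >= 1) return(-Inf)
      d <- sqrt(1 - rho)
      lZ <- log1p(-exp(-spec$lambda * sqrt(2)))
      log(spec$lambda) - spec$lambda * d - log(2 * d) - lZ
    },
    overdispersion = {
      psi <- value[1]
      if (psi <= 0) return(-Inf)
      # exponential on s = 1/psi, Jacobian |ds/dpsi| = 1/psi^2
      log(spec$lambda) - spec$lambda / psi - 2 * log(psi)
    },
    gaussian_fixed = stats::dnorm(value[1], spec$mean, spec$sd, log = TRUE))
}

#' Default prior set for the fern models
#'
#' Calibrations: spatio-temporal fields have P(range < 5000 m) = 0.1 and
#' P(sd > 2) = 0.5; AR(1) correlations have P(rho > 0) = 0.9; the spatially
#' varying year-trend field has P(range < 3000 m) = 0.5 and P(sd > 2) = 0.5;
#' fixed effects are Normal(0, 1000); cross-species trend scalings are
#' Normal(0, 10); overdispersion uses the exponential PC prior on 1/psi.
#'
#' @return Named list of \code{pc_prior} objects.
#' @export
default_priors <- function() {
  list(
    st_field = pc_prior("matern_range_sd", range0 = 5000, p_range_below = 0.1,
                        sigma0 = 2, p_sigma_above = 0.5),
    ar1 = pc_prior("ar1_correlation", rho0 = 0, p_above = 0.9),
    svc_field = pc_prior("matern_range_sd", range0 = 3000, p_range_below = 0.5,
                         sigma0 = 2, p_sigma_above = 0.5),
    overdispersion = pc_prior("overdispersion", inv_psi0 = 5, p_above = 0.1),
    fixed = pc_prior("gaussian_fixed", mean = 0, sd = 1000),
    svc_scaling = pc_prior("gaussian_fixed", mean = 0, sd = 10)
  )
}
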