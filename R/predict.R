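# Posterior prediction of the log-intensity surface and net change maps.

#' Predict the intensity surface from a fitted model
#'
#' Samples the latent state, evaluates the log-intensity eta for every domain
#' cell, requested year, and species through the mesh projector and covariate
#' design, and summarizes. Years outside the fitted range are refused
#' (temporal extrapolation needs extrapolated covariates supplied up front).
#'
#' @param result A \code{fern_fit}.
#' @param years Years to predict (default: all fitted years).
#' @param cells Cell ids (default: all).
#' @param n_samples Posterior samples (default 200).
#' @param seed Integer seed.
#' @param return_samples Attach the eta sample matrix (needed by
#'   \code{change_map}).
#' @return \code{fern_surface}: data.frame with per species/cell/year
#'   posterior mean, sd and 2.5/25/75/97.5 percent quantiles of eta and
#'   lambda = exp(eta).
#' @export
predict_intensity <- function(result, years = NULL, cells = NULL,
                              n_samples = 200L, seed = 1L,
                              return_samples = FALSE) {
  md <- result$model_data
  if (is.null(years)) years <- md$years
  if (!all(years %in% md$years))
    stop("prediction years outside the fitted range; supply extrapolated ",
         "covariates and refit to predict beyond it")
  if (is.null(cells)) cells <- md$domain$cells$cell_id
  grid <- expand.grid(cell_id = cells, year = years, species = 1:3)
  yix <- match(grid$year, md$years)
  dz <- make_design(md, grid$species, grid$cell_id, yix, "count")
  sm <- sample_posterior(result, n_samples, seed = seed)
  E <- as.matrix(dz$H0 %*% sm$latent)
  if (result$config$svc) {
    E <- E + as.matrix(dz$Hsvc2 %*% sm$latent) %*% diag(sm$b[1, ], n_samples) +
      as.matrix(dz$Hsvc3 %*% sm$latent) %*% diag(sm$b[2, ], n_samples)
  }
  qs <- t(apply(E, 1, stats::quantile, probs = c(0.025, 0.25, 0.75, 0.975)))
  out <- data.frame(grid,
                    eta_mean = rowMeans(E), eta_sd = apply(E, 1, stats::sd),
                    eta_q025 = qs[, 1], eta_q25 = qs[, 2], eta_q75 = qs[, 3],
                    eta_q975 = qs[, 4],
                    lambda_mean = rowMeans(exp(E)),
                    # exp() of very negative eta underflows; keep quantiles
                    # strictly positive as the intensity itself is
                    lambda_q025 = pmax(exp(qs[, 1]), .Machine$double.xmin),
                    lambda_q25 = pmax(exp(qs[, 2]), .Machine$double.xmin),
                    lambda_q75 = pmax(exp(qs[, 3]), .Machine$double.xmin),
                    lambda_q975 = pmax(exp(qs[, 4]), .Machine$double.xmin))
  if (return_samples) attr(out, "samples") <- E
  class(out) <- c("fern_surface", "data.frame")
  out
}

#' Net change in log-intensity between two years
#'
#' Per-sample differences eta(., year_b) - eta(., year_a) summarized per cell
#' and species; a cell is flagged significant when the credible interval for
#' the difference excludes zero.
#'
#' @param surface A \code{fern_surface} with attached samples
#'   (\code{predict_intensity(..., return_samples = TRUE)}).
#' @param year_a,year_b Years (both must be in the surface).
#' @param level Credible level (default 0.95).
#' @return data.frame: species, cell_id, mean, lower, upper, significant.
#' @export
change_map <- function(surface, year_a, year_b, level = 0.95) {
  E <- attr(surface, "samples")
  if (is.null(E)) stop("surface must carry samples (return_samples = TRUE)")
  if (!(year_a %in% surface$year) || !(year_b %in% surface$year))
    stop("both years must be present in the surface")
  a <- (1 - level) / 2
  ia <- which(surface$year == year_a)
  ib <- which(surface$year == year_b)
  key_a <- paste(surface$species[ia], surface$cell_id[ia])
  key_b <- paste(surface$species[ib], surface$cell_id[ib])
  ib <- ib[match(key_a, key_b)]
  D <- E[ib, , drop = FALSE] - E[ia, , drop = FALSE]
  lo <- apply(D, 1, stats::quantile, probs = a)
  hi <- apply(D, 1, stats::quantile, probs = 1 - a)
  data.frame(species = surface$species[ia], cell_id = surface$cell_id[ia],
             mean = rowMeans(D), lower = lo, upper = hi,
             significant = lo > 0 | hi < 0)
}
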