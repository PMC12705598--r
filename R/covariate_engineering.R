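# Covariate engineering: canopy heterogeneity (Rao's quadratic entropy),
# compositional transforms, collinearity screening, standardization, climate
# extrapolation, distance surfaces, and occurrence quality filters.

#' Rao's quadratic entropy of a height histogram
#'
#' Q = sum_i sum_j d_ij p_i p_j, the expected absolute (Euclidean, 1D)
#' difference between two height values drawn with replacement according to
#' their relative frequencies. Q >= 0 with equality iff all values coincide.
#'
#' @param values Numeric vector of (height) values.
#' @param frequencies Relative frequencies, same length, summing to 1.
#' @return Scalar Q.
#' @export
rao_q <- function(values, frequencies) {
  if (length(values) != length(frequencies))
    stop("values and frequencies must have the same length")
  if (any(!is.finite(values)) || any(frequencies < 0))
    stop("values must be finite and frequencies non-negative")
  if (abs(sum(frequencies) - 1) > 1e-8)
    stop("frequencies must sum to 1")
  d <- abs(outer(values, values, "-"))
  as.numeric(frequencies %*% d %*% frequencies)
}

#' Rao's Q over a moving window of grid cells
#'
#' Horizontal heterogeneity: for each cell, Rao's Q of the values of the cells
#' in a square window around it (window size in cells, odd).
#'
#' @param domain A \code{fern_domain}.
#' @param values Per-cell numeric vector (domain cell order).
#' @param window Odd window side in cells (default 3).
#' @return Per-cell Rao's Q vector.
#' @export
rao_q_window <- function(domain, values, window = 3L) {
  stopifnot(window %% 2 == 1, length(values) == nrow(domain$cells))
  nx <- domain$nx
  h <- (window - 1L) %/% 2L
  out <- numeric(length(values))
  m <- matrix(values, nx, nx)  # [ix, iy]
  for (iy in seq_len(nx)) for (ix in seq_len(nx)) {
    xs <- max(1L, ix - h):min(nx, ix + h)
    ys <- max(1L, iy - h):min(nx, iy + h)
    v <- as.vector(m[xs, ys])
    out[(iy - 1L) * nx + ix] <- rao_q(v, rep(1 / length(v), length(v)))
  }
  out
}

#' Helmert-basis contrast matrix for the ILR transform
#' @keywords internal
ilr_basis <- function(D) {
  V <- matrix(0, D, D - 1L)
  for (k in seq_len(D - 1L)) {
    V[seq_len(k), k] <- 1 / k
    V[k + 1L, k] <- -1
    V[, k] <- V[, k] * sqrt(k / (k + 1))
  }
  V
}

#' Isometric log-ratio transform of a composition
#'
#' Maps strictly positive parts (any total) to D-1 unconstrained coordinates
#' using a Helmert-style orthonormal basis; invariant to rescaling of the
#' input and exactly invertible by \code{ilr_inverse}.
#'
#' @param proportions Strictly positive parts (vector, or matrix with one
#'   composition per row).
#' @return Coordinates of length (or width) D-1, with the basis as attribute.
#' @export
ilr_transform <- function(proportions) {
  x <- rbind(proportions)
  if (ncol(x) < 2L) stop("a composition needs at least 2 parts")
  if (any(x <= 0))
    stop("all parts must be strictly positive; apply a zero-replacement first")
  V <- ilr_basis(ncol(x))
  lx <- log(x)
  clr <- lx - rowMeans(lx)
  z <- clr %*% V
  if (is.vector(proportions)) z <- drop(z)
  attr(z, "basis") <- V
  z
}

#' Inverse ILR transform
#' @param coords ILR coordinates (vector or matrix, D-1 columns).
#' @return Composition closed to sum 1.
#' @export
ilr_inverse <- function(coords) {
  z <- rbind(coords)
  V <- ilr_basis(ncol(z) + 1L)
  w <- exp(z %*% t(V))
  w <- w / rowSums(w)
  if (is.vector(coords)) drop(w) else w
}

#' Generalized variance inflation factors from the correlation matrix
#'
#' For one-degree-of-freedom covariates the GVIF equals the classical VIF,
#' computed as the diagonal of the inverse correlation matrix (the
#' determinant-ratio form det(R_k) det(R_-k) / det(R) specialised to scalar
#' blocks).
#'
#' @param X Numeric matrix/data.frame of covariates (columns).
#' @return Named vector of GVIFs.
#' @export
gvif <- function(X) {
  X <- as.matrix(X)
  R <- stats::cor(X)
  v <- diag(solve(R))
  names(v) <- colnames(X)
  v
}

#' Screen covariates for collinearity (pairwise correlation and GVIF)
#'
#' Constant covariates are flagged and excluded first. Pairs with |Pearson r|
#' above \code{r_max} are processed in descending |r|; within a pair the
#' covariate with the higher |correlation with abundance| is kept when an
#' abundance vector is supplied, otherwise the lexicographically first name.
#' Remaining covariates with GVIF above \code{gvif_max} are then dropped one
#' at a time (largest first, same tie-break).
#'
#' @param table data.frame/matrix of covariates (one column each).
#' @param abundance Optional numeric response used for tie-breaking.
#' @param r_max Pairwise correlation threshold (default 0.7).
#' @param gvif_max GVIF threshold (default 5).
#' @return List: \code{retained} (names), \code{dropped} (data.frame name,
#'   reason), \code{max_abs_r}, \code{max_gvif} diagnostics on the retained set.
#' @export
select_covariates <- function(table, abundance = NULL, r_max = 0.7, gvif_max = 5) {
  X <- as.data.frame(table)
  if (ncol(X) < 2L) stop("need at least 2 covariates")
  dropped <- data.frame(name = character(0), reason = character(0))
  const <- vapply(X, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)), TRUE)
  if (any(const)) {
    dropped <- rbind(dropped, data.frame(name = names(X)[const], reason = "constant"))
    X <- X[!const]
  }
  prefer <- function(a, b) {
    # returns name to KEEP
    if (!is.null(abundance)) {
      ca <- abs(stats::cor(X[[a]], abundance)); cb <- abs(stats::cor(X[[b]], abundance))
      if (abs(ca - cb) > 1e-12) return(if (ca > cb) a else b)
    }
    sort(c(a, b))[1]
  }
  repeat {
    if (ncol(X) < 2L) break
    R <- stats::cor(as.matrix(X))
    diag(R) <- 0
    if (max(abs(R)) <= r_max) break
    idx <- which(abs(R) == max(abs(R)), arr.ind = TRUE)[1, ]
    a <- colnames(R)[idx[1]]; b <- colnames(R)[idx[2]]
    keep <- prefer(a, b)
    drop <- setdiff(c(a, b), keep)
    dropped <- rbind(dropped, data.frame(name = drop, reason = sprintf("r>%g", r_max)))
    X <- X[setdiff(names(X), drop)]
  }
  repeat {
    if (ncol(X) < 2L) break
    g <- gvif(X)
    if (max(g) <= gvif_max) break
    worst <- names(g)[g == max(g)]
    worst <- if (length(worst) > 1L) {
      # drop the one the tie-break would NOT keep
      k <- worst[1]; for (w in worst[-1]) k <- prefer(k, w)
      setdiff(worst, k)[1]
    } else worst
    dropped <- rbind(dropped, data.frame(name = worst, reason = sprintf("gvif>%g", gvif_max)))
    X <- X[setdiff(names(X), worst)]
  }
  Rfin <- stats::cor(as.matrix(X)); diag(Rfin) <- 0
  list(retained = names(X), dropped = dropped,
       max_abs_r = if (ncol(X) > 1) max(abs(Rfin)) else 0,
       max_gvif = if (ncol(X) > 1) max(gvif(X)) else 1)
}

#' Z-score standardization with invertible metadata
#'
#' @param table data.frame of numeric covariates.
#' @return List: \code{table} (standardized), \code{center}, \code{scale}.
#'   Constant columns are rejected.
#' @export
standardize_covariates <- function(table) {
  X <- as.data.frame(table)
  s <- vapply(X, stats::sd, 0)
  if (any(s == 0)) stop("zero-variance covariate(s): ",
                        paste(names(X)[s == 0], collapse = ", "))
  m <- vapply(X, mean, 0)
  Z <- as.data.frame(mapply(function(v, mu, sd) (v - mu) / sd, X, m, s,
                            SIMPLIFY = FALSE))
  list(table = Z, center = m, scale = s)
}

#' Extend an annual climate series to later years
#'
#' \code{linear}: ordinary least-squares line through the observed years,
#' evaluated at the targets. \code{last_year}: final observed value repeated.
#' \code{mean}: observed-period average repeated. These mirror a primary
#' linear extrapolation and its two sensitivity alternatives.
#'
#' @param annual_series Named numeric vector (names = observed years) or
#'   data.frame with columns \code{year}, \code{value}.
#' @param target_years Integer years to estimate.
#' @param method One of \code{"linear"}, \code{"last_year"}, \code{"mean"}.
#' @return data.frame with columns \code{year}, \code{value} for the targets.
#' @export
extrapolate_climate <- function(annual_series, target_years,
                                method = c("linear", "last_year", "mean")) {
  method <- match.arg(method)
  if (is.data.frame(annual_series)) {
    yrs <- annual_series$year; val <- annual_series$value
  } else {
    yrs <- as.numeric(names(annual_series)); val <- as.numeric(annual_series)
  }
  if (any(!is.finite(yrs))) stop("observed years must be numeric")
  if (method == "linear" && length(yrs) < 2L)
    stop("linear extrapolation needs at least 2 observed years")
  out <- switch(method,
    linear = {
      fit <- stats::lm(val ~ yrs)
      unname(stats::predict(fit, data.frame(yrs = target_years)))
    },
    last_year = rep(val[which.max(yrs)], length(target_years)),
    mean = rep(mean(val), length(target_years)))
  data.frame(year = target_years, value = out)
}

#' Per-cell distance surface to line or point features
#'
#' Minimum Euclidean distance from each cell centroid to the features; the
#' \code{log} variant adds a floor of half the cell size before taking the
#' logarithm so on-feature cells stay finite.
#'
#' @param features Point matrix or list of 2x2 segment matrices (meters).
#' @param domain A \code{fern_domain}.
#' @param log Return log distance with floor (default FALSE).
#' @return Per-cell numeric vector (domain cell order).
#' @export
distance_surface <- function(features, domain, log = FALSE) {
  if (is.null(features) || (is.list(features) && length(features) == 0L) ||
      (is.matrix(features) && nrow(features) == 0L))
    stop("at least one feature is required")
  d <- min_feature_distance(as.matrix(domain$cells[, c("x", "y")]), features)
  if (log) log(d + domain$cell_size / 2) else d
}

#' Quality filters for opportunistic occurrence records
#'
#' Applies, in order: (1) valid finite coordinates; (2) exclusion of fossil /
#' cultivated (living) basis-of-record; (3) exclusion of placeholder
#' coordinate-uncertainty values; (4) exclusion of coordinate resolution
#' coarser than the threshold (degrees); (5) exclusion of coordinate
#' uncertainty above the threshold (m). Records whose uncertainty or
#' resolution metadata are absent are retained by rules 3-5.
#'
#' @param records data.frame with columns \code{lon}, \code{lat}; optional
#'   \code{uncertainty_m}, \code{resolution_deg}, \code{basis_of_record}.
#' @param rules List of thresholds: \code{placeholder_uncertainty}
#'   (default c(301, 3036, 999, 9999)), \code{max_uncertainty_m} (1000),
#'   \code{max_resolution_deg} (0.01), \code{excluded_basis}
#'   (c("FOSSIL_SPECIMEN", "LIVING_SPECIMEN")).
#' @return List: \code{retained} (data.frame), \code{rejections} (named counts
#'   per rule, summing to input minus retained).
#' @export
filter_occurrences <- function(records, rules = list()) {
  def <- list(placeholder_uncertainty = c(301, 3036, 999, 9999),
              max_uncertainty_m = 1000, max_resolution_deg = 0.01,
              excluded_basis = c("FOSSIL_SPECIMEN", "LIVING_SPECIMEN"))
  rules <- utils::modifyList(def, rules)
  rej <- c(invalid_coordinates = 0L, basis_of_record = 0L,
           placeholder_uncertainty = 0L, coarse_resolution = 0L,
           high_uncertainty = 0L)
  keep <- rep(TRUE, nrow(records))
  bad <- !is.finite(records$lon) | !is.finite(records$lat)
  rej["invalid_coordinates"] <- sum(bad & keep); keep <- keep & !bad
  if (!is.null(records$basis_of_record)) {
    bad <- records$basis_of_record %in% rules$excluded_basis
    rej["basis_of_record"] <- sum(bad & keep); keep <- keep & !bad
  }
  unc <- if (is.null(records$uncertainty_m)) rep(NA_real_, nrow(records)) else records$uncertainty_m
  bad <- !is.na(unc) & unc %in% rules$placeholder_uncertainty
  rej["placeholder_uncertainty"] <- sum(bad & keep); keep <- keep & !bad
  res <- if (is.null(records$resolution_deg)) rep(NA_real_, nrow(records)) else records$resolution_deg
  bad <- !is.na(res) & res > rules$max_resolution_deg
  rej["coarse_resolution"] <- sum(bad & keep); keep <- keep & !bad
  bad <- !is.na(unc) & unc > rules$max_uncertainty_m
  rej["high_uncertainty"] <- sum(bad & keep); keep <- keep & !bad
  list(retained = records[keep, , drop = FALSE], rejections = rej)
}
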