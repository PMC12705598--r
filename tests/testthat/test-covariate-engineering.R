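test_that("Rao's Q matches closed forms and the double-sum oracle", {
  expect_equal(rao_q(c(5, 5, 5), rep(1 / 3, 3)), 0)
  expect_equal(rao_q(c(3, 4), c(0.5, 0.5)), 0.5)
  set.seed(1)
  v <- sample(0:30, 12)
  p <- runif(12); p <- p / sum(p)
  oracle <- 0
  for (i in 1:12) for (j in 1:12) oracle <- oracle + abs(v[i] - v[j]) * p[i] * p[j]
  expect_equal(rao_q(v, p), oracle, tolerance = 1e-12)
  # permutation invariance of (value, frequency) pairs
  perm <- sample(12)
  expect_equal(rao_q(v[perm], p[perm]), rao_q(v, p), tolerance = 1e-12)
  expect_error(rao_q(1:3, c(0.5, 0.5)), "length")
  expect_error(rao_q(1:2, c(0.3, 0.3)), "sum to 1")
})

test_that("ILR transform is scale-invariant and exactly invertible", {
  expect_equal(as.vector(ilr_transform(rep(0.25, 4))), rep(0, 3))
  x <- c(0.1, 0.25, 0.3, 0.35)
  expect_equal(as.vector(ilr_transform(7.3 * x)), as.vector(ilr_transform(x)))
  set.seed(2)
  for (i in 1:10) {
    comp <- runif(5); comp <- comp / sum(comp)
    expect_equal(as.vector(ilr_inverse(ilr_transform(comp))), comp,
                 tolerance = 1e-12)
  }
  expect_error(ilr_transform(c(0.5, 0, 0.5)), "zero-replacement")
})

test_that("covariate screening removes collinear sets like the oracles", {
  set.seed(3)
  n <- 300
  a <- rnorm(n); b <- rnorm(n); c <- rnorm(n)
  # duplicated covariate: exactly one copy kept
  sel <- select_covariates(data.frame(a = a, a2 = a, b = b))
  expect_length(sel$retained, 2)
  expect_true("b" %in% sel$retained)
  # orthogonal (mean-centered) covariates all kept with unit GVIF
  X <- unclass(stats::poly(seq_len(n), 3))
  sel2 <- select_covariates(data.frame(X))
  expect_length(sel2$retained, 3)
  expect_equal(unname(gvif(X)), rep(1, 3), tolerance = 1e-8)
  # one pair over threshold: result matches exhaustive search for the
  # largest subset with all |r| <= 0.7 (tie-broken lexicographically)
  x1 <- rnorm(n)
  x2 <- 0.77 * x1 + sqrt(1 - 0.77^2) * rnorm(n)
  x3 <- rnorm(n)
  df <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  sel3 <- select_covariates(df)
  ok_subset <- function(nms) {
    if (length(nms) < 2) return(TRUE)
    R <- abs(stats::cor(df[nms])); diag(R) <- 0
    max(R) <= 0.7
  }
  subsets <- unlist(lapply(3:1, function(k)
    combn(names(df), k, simplify = FALSE)), recursive = FALSE)
  best <- Filter(ok_subset, subsets)[[1]]
  expect_equal(length(sel3$retained), length(best))
  expect_true(ok_subset(sel3$retained))
  expect_true(sel3$max_abs_r <= 0.7)
  expect_true(sel3$max_gvif <= 5)
  # constant covariate flagged and excluded
  sel4 <- select_covariates(data.frame(a = a, k = rep(1, n), b = b))
  expect_true("k" %in% sel4$dropped$name)
})

test_that("GVIF agrees with the car package on a regression fit", {
  skip_if_not_installed("car")
  set.seed(4)
  n <- 200
  X <- data.frame(u = rnorm(n), v = rnorm(n))
  X$w <- 0.6 * X$u + 0.4 * rnorm(n)
  y <- rnorm(n)
  fit <- lm(y ~ u + v + w, data = X)
  expect_equal(unname(gvif(X)), unname(car::vif(fit)), tolerance = 1e-8)
})

test_that("standardization is exact and invertible", {
  set.seed(5)
  tab <- data.frame(p = rnorm(50, 3, 2), q = runif(50))
  std <- standardize_covariates(tab)
  expect_equal(sapply(std$table, mean), c(p = 0, q = 0), tolerance = 1e-9)
  expect_equal(sapply(std$table, sd), c(p = 1, q = 1), tolerance = 1e-9)
  back <- mapply(function(z, m, s) z * s + m, std$table, std$center, std$scale)
  expect_equal(unname(back[, 1]), tab$p, tolerance = 1e-12)
  expect_error(standardize_covariates(data.frame(a = rep(2, 5))), "zero-variance")
})

test_that("climate extrapolation follows the three stated rules", {
  ser <- data.frame(year = 2014:2019, value = 1:6)
  expect_equal(extrapolate_climate(ser, 2020, "linear")$value, 7)
  expect_equal(extrapolate_climate(ser, 2020:2023, "last_year")$value, rep(6, 4))
  expect_equal(extrapolate_climate(ser, 2020:2023, "mean")$value, rep(3.5, 4))
  expect_error(extrapolate_climate(data.frame(year = 2014, value = 1),
                                   2015, "linear"), "at least 2")
})

test_that("distance surfaces match brute force and handle the log floor", {
  d <- generate_domain(1, 500, 100, 2)
  pt <- matrix(c(50, 50), 1, 2)  # first cell centroid
  ds <- distance_surface(pt, d)
  expect_equal(ds[1], 0)
  expect_equal(distance_surface(matrix(c(0, 0), 1, 2), d)[1], sqrt(50^2 + 50^2))
  ld <- distance_surface(pt, d, log = TRUE)
  expect_equal(ld[1], log(50))  # floor = half the cell size
  expect_error(distance_surface(list(), d), "at least one")
})

test_that("occurrence filters enumerate rejections exactly", {
  rec <- data.frame(
    lon = c(NA, rep(1, 19)), lat = rep(1, 20),
    uncertainty_m = c(100, 9999, 301, 999, 3036, 1500, 1000, NA, NA, 50,
                      rep(10, 10)),
    resolution_deg = c(rep(NA, 10), 0.02, 0.5, rep(0.001, 8)),
    basis_of_record = c(rep("HUMAN_OBSERVATION", 13), "FOSSIL_SPECIMEN",
                        "LIVING_SPECIMEN", rep("HUMAN_OBSERVATION", 5)))
  out <- filter_occurrences(rec)
  # hand enumeration: row1 bad coords; rows 2-5 placeholders; row 6 >1000 m;
  # rows 11-12 coarse resolution; rows 14-15 basis of record
  expect_equal(unname(out$rejections["invalid_coordinates"]), 1L)
  expect_equal(unname(out$rejections["placeholder_uncertainty"]), 4L)
  expect_equal(unname(out$rejections["high_uncertainty"]), 1L)
  expect_equal(unname(out$rejections["coarse_resolution"]), 2L)
  expect_equal(unname(out$rejections["basis_of_record"]), 2L)
  expect_equal(nrow(out$retained), 10L)
  expect_equal(sum(out$rejections), nrow(rec) - nrow(out$retained))
  # absent uncertainty metadata is retained; uncertainty exactly 1000 kept
  expect_true(any(is.na(out$retained$uncertainty_m)))
  expect_true(1000 %in% out$retained$uncertainty_m)
})
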