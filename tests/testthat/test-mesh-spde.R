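test_that("mesh construction honors edge, cutoff and extension constraints", {
  d <- generate_domain(1, 100, 10, 2)  # unit-square-like domain, /10 scale
  m <- build_mesh(d, max_edge_inner = 100, max_edge_outer = 200,
                  extension = 200, cutoff = 20)
  el <- mesh_edge_lengths(m)
  expect_true(all(el$interior <= 100 + 1e-9))
  # minimum inter-node distance >= cutoff (lattice spacing)
  expect_true(m$spacing >= 20)
  # extension ring present: mesh bbox contains boundary buffered by extension
  expect_true(m$bbox[1] <= 0 - 200 + 1e-9 && m$bbox[2] >= 100 + 200 - 1e-9)
  # all triangles non-degenerate
  areas <- apply(m$tv, 1, function(v)
    polygon_area(m$loc[v, , drop = FALSE]))
  expect_true(all(areas > 0))
  expect_error(build_mesh(cbind(0, 0), 100), "at least 3")
  expect_error(build_mesh(d, max_edge_inner = 10, cutoff = 50), "cutoff")
})

test_that("projector rows are barycentric weights reproducing linear fields", {
  d <- generate_domain(1, 1000, 100, 2)
  m <- build_mesh(d, 300, 600, 200, 30)
  pts <- cbind(runif(25, 0, 1000), runif(25, 0, 1000))
  A <- projector(m, pts)
  expect_equal(unname(Matrix::rowSums(A)), rep(1, 25), tolerance = 1e-12)
  # location at a node -> single unit weight
  Anode <- projector(m, m$loc[10, , drop = FALSE])
  expect_equal(max(Anode), 1, tolerance = 1e-12)
  expect_equal(Matrix::nnzero(Anode > 1e-12), 1)
  # linear-in-coordinates nodal field is reproduced exactly
  f <- 2 + 0.3 * m$loc[, 1] - 0.7 * m$loc[, 2]
  expect_equal(as.vector(A %*% f), 2 + 0.3 * pts[, 1] - 0.7 * pts[, 2],
               tolerance = 1e-8)
  expect_error(projector(m, cbind(1e6, 1e6)), "outside")
})

test_that("SPDE precision is SPD with the stated marginal sd and range", {
  d <- generate_domain(1, 3000, 300, 2)
  m <- mesh_with_fem(build_mesh(d, 400, 800, 1200, 20))
  Q <- spde_precision(m, range_m = 800, sigma = 1.5)
  expect_true(Matrix::isSymmetric(Q))
  expect_silent(Matrix::Cholesky(Q))  # positive definite
  S <- solve(as.matrix(Q))
  ctr <- which.min(colSums((t(m$loc) - c(1500, 1500))^2))
  expect_equal(sqrt(S[ctr, ctr]), 1.5, tolerance = 0.1)
  # correlation at one range drops to ~0.13
  dists <- sqrt(colSums((t(m$loc) - m$loc[ctr, ])^2))
  far <- which.min(abs(dists - 800))
  corr <- S[ctr, far] / sqrt(S[ctr, ctr] * S[far, far])
  expect_lt(abs(corr - 0.13), 0.04)
  expect_error(spde_precision(m, -5, 1), "positive")
})

test_that("AR(1) precision inverts to the geometric correlation", {
  expect_equal(as.matrix(ar1_precision(3, 0)), diag(3))
  rho <- 0.6
  Q2 <- as.matrix(ar1_precision(2, rho))
  expect_equal(Q2, matrix(c(1, -rho, -rho, 1), 2) / (1 - rho^2))
  Q <- ar1_precision(7, -0.45)
  S <- solve(as.matrix(Q))
  oracle <- outer(1:7, 1:7, function(i, j) (-0.45)^abs(i - j))
  expect_equal(S, oracle, tolerance = 1e-10)
  expect_error(ar1_precision(4, 1), "rho")
})

test_that("Kronecker space-time precision separates space and time", {
  d <- generate_domain(1, 1000, 200, 2)
  m <- mesh_with_fem(build_mesh(d, 600, 1200, 400, 20))
  Qs <- spde_precision(m, 500, 1)
  Qt <- ar1_precision(3, 0.5)
  Qst <- kronecker_st_precision(Qs, Qt)
  expect_equal(nrow(Qst), nrow(Qs) * 3)
  expect_equal(as.matrix(Qst), kronecker(as.matrix(Qt), as.matrix(Qs)),
               tolerance = 1e-12)
  S <- solve(as.matrix(Qst))
  Ss <- solve(as.matrix(Qs)); St <- solve(as.matrix(Qt))
  ns <- nrow(Qs)
  i <- 3; j <- 11  # two space nodes; times 1 and 3
  lhs <- S[i, 2 * ns + j] / sqrt(S[i, i] * S[2 * ns + j, 2 * ns + j])
  rhs <- (Ss[i, j] / sqrt(Ss[i, i] * Ss[j, j])) * (St[1, 3] / sqrt(St[1, 1] * St[3, 3]))
  expect_equal(lhs, rhs, tolerance = 1e-8)
  expect_error(kronecker_st_precision(Qs, ar1_precision(1e4, 0.1)), "max_dim")
})

test_that("precision builders are exactly symmetric and sampling matches the
          dense covariance", {
  d <- generate_domain(1, 800, 200, 2)
  m <- mesh_with_fem(build_mesh(d, 500, 1000, 300, 10))
  Q <- spde_precision(m, 400, 1)
  expect_equal(max(abs(Q - Matrix::t(Q))), 0)
  Qt <- ar1_precision(5, 0.7)
  expect_equal(max(abs(Qt - Matrix::t(Qt))), 0)
  set.seed(99)
  X <- sample_gmrf(Qt, 5000)
  expect_equal(stats::cov(t(X)), as.matrix(solve(as.matrix(Qt))),
               tolerance = 0.08)
})

test_that("meshes and precision matrices round-trip through disk", {
  d <- generate_domain(1, 800, 200, 2)
  m <- mesh_with_fem(build_mesh(d, 500, 1000, 300, 10))
  dir <- withr::local_tempdir()
  write_mesh_csv(m, file.path(dir, "nodes.csv"), file.path(dir, "tri.csv"))
  m2 <- read_mesh_csv(file.path(dir, "nodes.csv"), file.path(dir, "tri.csv"))
  expect_equal(m2$loc, unname(m$loc))
  expect_equal(m2$tv, unname(m$tv))
  # identical FEM precision from the reloaded mesh
  Q1 <- spde_precision(m, 400, 1)
  Q2 <- spde_precision(mesh_with_fem(m2), 400, 1)
  expect_equal(as.matrix(Q1), as.matrix(Q2), tolerance = 1e-12)
  write_precision_mtx(Q1, file.path(dir, "Q.mtx"))
  Q3 <- Matrix::readMM(file.path(dir, "Q.mtx"))
  expect_equal(as.matrix(Q3), unname(as.matrix(Q1)), tolerance = 1e-12)
})

test_that("SPDE sparsity grows linearly with node count", {
  nn <- sapply(c(800, 1600), function(ext) {
    d <- generate_domain(1, ext, 200, 2)
    m <- mesh_with_fem(build_mesh(d, 250, 500, 200, 10))
    Q <- spde_precision(m, 400, 1)
    c(nodes = nrow(m$loc), nnz = Matrix::nnzero(Q))
  })
  dens <- nn["nnz", ] / nn["nodes", ]
  # nonzeros per node roughly constant (two-ring stencil)
  expect_lt(abs(dens[2] - dens[1]) / dens[1], 0.35)
})
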