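# Sparse GMRF building blocks: finite-element Matern (SPDE) precision, AR(1)
# precision, their Kronecker space-time product, and Cholesky sampling.

#' Finite-element matrices (lumped mass C, stiffness G) of a mesh
#' @keywords internal
fem_matrices <- function(mesh) {
  loc <- mesh$loc; tv <- mesh$tv
  nt <- nrow(tv); nn <- nrow(loc)
  Ci <- numeric(nn)
  gi <- gj <- gx <- vector("list", nt)
  for (t in seq_len(nt)) {
    v <- tv[t, ]
    p <- loc[v, , drop = FALSE]
    e1 <- p[3, ] - p[2, ]; e2 <- p[1, ] - p[3, ]; e3 <- p[2, ] - p[1, ]
    area2 <- e3[1] * (-e2[2]) - e3[2] * (-e2[1])  # 2A (signed)
    A <- abs(area2) / 2
    if (A <= 0) stop("degenerate triangle in mesh")
    Ci[v] <- Ci[v] + A / 3
    E <- rbind(e1, e2, e3)
    Gt <- (E %*% t(E)) / (4 * A)
    gi[[t]] <- rep(v, each = 3L)
    gj[[t]] <- rep(v, times = 3L)
    gx[[t]] <- as.vector(t(Gt))
  }
  G <- Matrix::sparseMatrix(i = unlist(gi), j = unlist(gj), x = unlist(gx),
                            dims = c(nn, nn))
  list(C = Matrix::Diagonal(x = Ci), G = Matrix::forceSymmetric((G + Matrix::t(G)) / 2))
}

#' Matern SPDE precision matrix on a mesh
#'
#' GMRF approximation of a Matern field with smoothness nu = 1 (alpha = 2 in
#' two dimensions). The range follows the convention kappa = sqrt(8 nu)/range,
#' i.e. the distance at which spatial correlation drops to approximately 0.13.
#' The marginal variance away from the boundary is \code{sigma^2}:
#' sigma^2 = 1 / (4 pi kappa^2 tau^2).
#'
#' @param mesh A \code{fern_mesh}.
#' @param range_m Spatial range in meters (> 0).
#' @param sigma Marginal standard deviation (> 0).
#' @return Sparse symmetric positive-definite \code{dsCMatrix} with attributes
#'   \code{range}, \code{sigma}.
#' @export
spde_precision <- function(mesh, range_m, sigma) {
  if (!is.numeric(range_m) || range_m <= 0 || !is.numeric(sigma) || sigma <= 0)
    stop("range_m and sigma must be positive")
  fem <- if (!is.null(mesh$fem)) mesh$fem else fem_matrices(mesh)
  kappa <- sqrt(8) / range_m
  tau2 <- 1 / (4 * pi * kappa^2 * sigma^2)
  Cinv <- Matrix::Diagonal(x = 1 / Matrix::diag(fem$C))
  G2 <- fem$G %*% Cinv %*% fem$G
  Q <- tau2 * (kappa^4 * fem$C + 2 * kappa^2 * fem$G + G2)
  Q <- Matrix::forceSymmetric(Q)
  attr(Q, "range") <- range_m
  attr(Q, "sigma") <- sigma
  Q
}

#' Attach cached finite-element matrices to a mesh
#' @param mesh A \code{fern_mesh}.
#' @return The mesh with a \code{fem} element.
#' @export
mesh_with_fem <- function(mesh) {
  if (is.null(mesh$fem)) mesh$fem <- fem_matrices(mesh)
  mesh
}

#' AR(1) precision matrix with unit marginal variance
#'
#' Tridiagonal precision of a stationary first-order autoregression scaled so
#' every marginal variance equals one; the Matern sigma of a Kronecker
#' space-time field is then its marginal standard deviation.
#'
#' @param n_times Number of time points (>= 1).
#' @param rho Lag-one autocorrelation, |rho| < 1.
#' @return Sparse symmetric \code{n_times} x \code{n_times} precision matrix.
#' @export
ar1_precision <- function(n_times, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (n_times < 1) stop("n_times must be >= 1")
  if (n_times == 1L) return(Matrix::Diagonal(x = 1))
  d <- c(1, rep(1 + rho^2, n_times - 2L), 1)
  Q <- Matrix::bandSparse(n_times, k = c(0L, 1L),
                          diagonals = list(d, rep(-rho, n_times - 1L)),
                          symmetric = TRUE)
  Matrix::forceSymmetric(Q / (1 - rho^2))
}

#' Kronecker space-time precision
#'
#' Separable precision of a spatio-temporal field stored year-major (all mesh
#' nodes of year 1, then year 2, ...): Q = Q_time %x% Q_space.
#'
#' @param Q_space Sparse spatial precision (e.g. from \code{spde_precision}).
#' @param Q_time Sparse temporal precision (e.g. from \code{ar1_precision}).
#' @param max_dim Guard against accidental huge products.
#' @return Sparse symmetric precision of dimension nrow(Q_space)*nrow(Q_time).
#' @export
kronecker_st_precision <- function(Q_space, Q_time, max_dim = 2e5) {
  n <- nrow(Q_space) * nrow(Q_time)
  if (n > max_dim) stop("space-time dimension ", n, " exceeds max_dim guard")
  Matrix::forceSymmetric(Q_time %x% Q_space)
}

#' Sample a zero-mean GMRF from its sparse precision
#'
#' Draws via the permuted Cholesky factor: if Q = P' L L' P, solving
#' L' v = z and unpermuting gives Var(x) = Q^{-1}.
#'
#' @param Q Sparse symmetric positive-definite precision.
#' @param n Number of samples.
#' @return Matrix with \code{n} columns, one sample per column.
#' @export
sample_gmrf <- function(Q, n = 1L) {
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Q), LDL = FALSE, perm = TRUE)
  z <- matrix(stats::rnorm(nrow(Q) * n), nrow(Q), n)
  v <- Matrix::solve(ch, z, system = "Lt")
  as.matrix(Matrix::solve(ch, v, system = "Pt"))
}

#' Log-determinant of a sparse symmetric positive-definite matrix
#' @keywords internal
logdet_spd <- function(Q) {
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Q), LDL = FALSE, perm = TRUE)
  2 * Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus[[1]]
}

#' Write a sparse matrix in MatrixMarket format
#' @param Q Sparse matrix.
#' @param path Output .mtx path.
#' @export
write_precision_mtx <- function(Q, path) {
  Matrix::writeMM(methods::as(methods::as(Q, "generalMatrix"), "CsparseMatrix"), path)
  invisible(path)
}

#' Write a mesh as a node/triangle CSV pair
#' @param mesh A \code{fern_mesh}.
#' @param nodes_path,triangles_path Output CSV paths.
#' @export
write_mesh_csv <- function(mesh, nodes_path, triangles_path) {
  utils::write.csv(data.frame(node = seq_len(nrow(mesh$loc)),
                              x = mesh$loc[, 1], y = mesh$loc[, 2],
                              interior = mesh$interior),
                   nodes_path, row.names = FALSE)
  utils::write.csv(data.frame(v1 = mesh$tv[, 1], v2 = mesh$tv[, 2],
                              v3 = mesh$tv[, 3]),
                   triangles_path, row.names = FALSE)
  invisible(c(nodes_path, triangles_path))
}

#' Read a mesh from its node/triangle CSV pair
#' @param nodes_path,triangles_path CSV paths from \code{write_mesh_csv}.
#' @return A \code{fern_mesh} (without cached finite-element matrices).
#' @export
read_mesh_csv <- function(nodes_path, triangles_path) {
  nd <- utils::read.csv(nodes_path)
  tv <- as.matrix(utils::read.csv(triangles_path))
  loc <- cbind(nd$x, nd$y)
  structure(list(loc = loc, tv = unname(tv), interior = nd$interior,
                 spacing = NA_real_,
                 bbox = c(range(loc[, 1]), range(loc[, 2]))),
            class = "fern_mesh")
}

#' Edge lengths of a mesh, split into interior and extension edges
#' @param mesh A \code{fern_mesh}.
#' @return List with numeric vectors \code{interior} and \code{outer}.
#' @export
mesh_edge_lengths <- function(mesh) {
  tv <- mesh$tv
  ed <- rbind(tv[, 1:2], tv[, 2:3], tv[, c(3, 1)])
  ed <- unique(t(apply(ed, 1, sort)))
  len <- sqrt(rowSums((mesh$loc[ed[, 1], , drop = FALSE] -
                         mesh$loc[ed[, 2], , drop = FALSE])^2))
  inner <- mesh$interior[ed[, 1]] & mesh$interior[ed[, 2]]
  list(interior = len[inner], outer = len[!inner])
}
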