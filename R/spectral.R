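#' Choose the RBF kernel scale sigma
#'
#' The scale of the radial basis function kernel is not identifiable from
#' first principles; the default is the median heuristic: the median of all
#' N(N-1)/2 pairwise Euclidean feature distances (exact for N <= 2000,
#' otherwise computed over a seeded subsample of 2000 voxels).
#'
#' @param fm a `feature_matrix` (or bare numeric matrix).
#' @param rule `"median"` or `"fixed"`.
#' @param value the sigma to return under the fixed rule.
#' @param seed seed for the subsample drawn when N > 2000.
#' @return positive scalar sigma with attribute `rule`.
#' @export
choose_sigma <- function(fm, rule = c("median", "fixed"), value = NULL,
                         seed = 1L) {
  rule <- match.arg(rule)
  if (rule == "fixed") {
    if (is.null(value) || !is.finite(value) || value <= 0)
      stop("fixed sigma rule requires a positive value")
    return(structure(as.double(value), rule = "fixed"))
  }
  X <- if (inherits(fm, "feature_matrix")) fm$X else as.matrix(fm)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 voxels to choose sigma")
  if (n > 2000L) {
    idx <- withr::with_seed(seed, sample.int(n, 2000L))
    X <- X[idx, , drop = FALSE]
  }
  d <- as.vector(stats::dist(X))
  med <- stats::median(d)
  if (med <= 0) stop("degenerate features: all pairwise distances are zero")
  structure(med, rule = "median")
}

#' RBF affinity matrix
#'
#' W_ij = exp(-||x_i - x_j||^2 / (2 sigma^2)) for i != j and W_ii = 0:
#' a symmetric nonnegative voxel-similarity matrix with entries in [0,1].
#'
#' @param fm a `feature_matrix` (or bare numeric matrix of features).
#' @param sigma positive RBF scale, e.g. from [choose_sigma()].
#' @return object of class `affinity_matrix`: `W` (N x N), `sigma`,
#'   `sigma_rule`.
#' @export
compute_affinity <- function(fm, sigma) {
  X <- if (inherits(fm, "feature_matrix")) fm$X else as.matrix(fm)
  if (nrow(X) < 2L) stop("need at least 2 voxels")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  D2 <- as.matrix(stats::dist(X))^2
  if (any(!is.finite(D2))) stop("non-finite pairwise distances")
  W <- exp(-D2 / (2 * sigma^2))
  diag(W) <- 0
  dimnames(W) <- NULL
  structure(list(W = W, sigma = as.double(sigma),
                 sigma_rule = attr(sigma, "rule") %||% "fixed"),
            class = "affinity_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sparsify an affinity matrix to mutual/union k nearest neighbors
#'
#' Keeps W_ij iff j is among the m largest affinities of i or i is among the
#' m largest of j (symmetrized union); everything else is set to zero. This
#' is the scalability escape hatch for large N; symmetry, zero diagonal and
#' the [0,1] range are preserved.
#'
#' @param A an `affinity_matrix`.
#' @param m neighbors to keep per voxel, 1 <= m < N.
#' @return sparsified `affinity_matrix`.
#' @export
knn_sparsify <- function(A, m) {
  stopifnot(inherits(A, "affinity_matrix"))
  W <- A$W
  n <- nrow(W)
  if (m < 1L || m >= n) stop("need 1 <= m < N")
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(W[i, ], decreasing = TRUE)[seq_len(m)]
    keep[i, ord] <- TRUE
  }
  keep <- keep | t(keep)
  W[!keep] <- 0
  diag(W) <- 0
  A$W <- W
  A
}

#' Spectral embedding from the normalized graph Laplacian
#'
#' Forms the degree-normalized Laplacian of the affinity graph and returns
#' the eigenvectors of its k smallest eigenvalues as embedding coordinates.
#' The symmetric variant is L_sym = I - D^{-1/2} W D^{-1/2}; the random-walk
#' variant rescales the eigenvectors by D^{-1/2}. Eigenvector sign is fixed
#' deterministically (first component of magnitude > 1e-9 made positive).
#' Voxels with degree < 1e-12 are treated as isolated (their normalizer is
#' zeroed and they are reported); more than 5% isolated voxels is an error
#' suggesting a larger sigma.
#'
#' @param A an `affinity_matrix`.
#' @param k number of eigenvectors (1 <= k <= N).
#' @param row_normalize scale each embedding row to unit Euclidean norm
#'   (rows with norm < 1e-12 are left at zero and flagged).
#' @param laplacian `"sym"` or `"rw"`.
#' @return object of class `spectral_embedding`: `Y` (N x k), `eigenvalues`
#'   (ascending, in [0,2]), `row_normalized`, `isolated` (indices),
#'   `zero_rows` (indices left unnormalized).
#' @export
spectral_embed <- function(A, k, row_normalize = TRUE,
                           laplacian = c("sym", "rw")) {
  stopifnot(inherits(A, "affinity_matrix"))
  laplacian <- match.arg(laplacian)
  W <- A$W
  n <- nrow(W)
  if (k > n) stop("k must not exceed the number of voxels")
  d <- rowSums(W)
  isolated <- which(d < 1e-12)
  if (length(isolated) > 0.05 * n)
    stop("more than 5% of voxels are isolated in the affinity graph; ",
         "increase sigma")
  dinv <- ifelse(d < 1e-12, 0, 1 / sqrt(d))
  M <- W * (dinv %o% dinv)
  L <- diag(n) - M
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  sel <- n:(n - k + 1L)                       # eigen() sorts descending
  vals <- eig$values[sel]
  V <- eig$vectors[, sel, drop = FALSE]
  for (j in seq_len(k)) {
    nz <- which(abs(V[, j]) > 1e-9)
    if (length(nz) && V[nz[1L], j] < 0) V[, j] <- -V[, j]
  }
  if (laplacian == "rw") V <- V * dinv
  zero_rows <- integer(0)
  if (row_normalize) {
    rn <- sqrt(rowSums(V^2))
    zero_rows <- which(rn < 1e-12)
    rn[rn < 1e-12] <- 1
    V <- V / rn
  }
  structure(list(Y = V, eigenvalues = vals,
                 row_normalized = isTRUE(row_normalize),
                 laplacian = laplacian, isolated = isolated,
                 zero_rows = zero_rows),
            class = "spectral_embedding")
}
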