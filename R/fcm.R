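#' Fuzzy C-means clustering
#'
#' Baseline soft clusterer with the standard alternating updates: membership
#' u_ik = 1 / sum_j (d_ik / d_jk)^{2/(m-1)} and centroids as the u^m-weighted
#' means. A point coincident with one or more centroids (distance < 1e-12)
#' gets crisp membership on the nearest such centroid. The objective
#' J_m = sum_ik u_ik^m d_ik^2 is non-increasing and its trace is returned.
#'
#' @param Y N x d numeric matrix.
#' @param K number of clusters.
#' @param m fuzziness exponent, > 1 (field-standard default 2).
#' @param tol relative objective-change stopping tolerance.
#' @param max_iter iteration cap.
#' @param seed seed for the spread-out centroid initialization.
#' @return list with `centroids` (K x d), `U` (N x K memberships, rows sum
#'   to 1), `objective` (trace), `iterations`.
#' @export
fcm_fit <- function(Y, K, m = 2, tol = 1e-6, max_iter = 200L, seed = 1L) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < K) stop("need at least K points")
  if (m <= 1) stop("fuzziness m must exceed 1")
  if (any(!is.finite(Y))) stop("non-finite input")
  cent <- withr::with_seed(seed, {
    idx <- sample.int(n, 1L)
    cent <- Y[idx, , drop = FALSE]
    while (nrow(cent) < K) {
      mind <- apply(.sqdist_to(Y, cent), 1L, min)
      cent <- rbind(cent, Y[which.max(mind), , drop = FALSE])
    }
    cent
  })
  U <- .fcm_memberships(Y, cent, m)
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    Um <- U^m
    cent <- (t(Um) %*% Y) / colSums(Um)
    U <- .fcm_memberships(Y, cent, m)
    d2 <- .sqdist_to(Y, cent)
    obj <- c(obj, sum(U^m * d2))
    if (it > 1L) {
      rel <- abs(obj[it] - obj[it - 1L]) / max(abs(obj[it - 1L]), 1e-300)
      if (rel < tol) break
    }
  }
  list(centroids = cent, U = U, objective = obj, iterations = it)
}

.fcm_memberships <- function(Y, cent, m) {
  d2 <- .sqdist_to(Y, cent)
  d2 <- pmax(d2, 0)
  U <- matrix(0, nrow(Y), nrow(cent))
  coincident <- d2 < 1e-24                 # squared distance < (1e-12)^2
  hit <- rowSums(coincident) > 0L
  if (any(hit)) {
    nearest <- max.col(-d2[hit, , drop = FALSE], ties.method = "first")
    U[cbind(which(hit), nearest)] <- 1
  }
  reg <- which(!hit)
  if (length(reg)) {
    p <- 1 / (m - 1)
    inv <- d2[reg, , drop = FALSE]^(-p)    # u_ik = d_ik^{-2/(m-1)} / sum_j d_ij^{-2/(m-1)}
    U[reg, ] <- inv / rowSums(inv)
  }
  U
}
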