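#' Mixture-model initialization
#'
#' @param Y N x d numeric matrix.
#' @param K number of components.
#' @param strategy `"kmeans"` (default: K-means centroids, uniform weights,
#'   pooled diagonal covariance) or `"random"` (seeded random
#'   responsibilities followed by one M-step).
#' @param seed integer seed.
#' @return list of class `init_spec` with `pi`, `mu` (K x d), `Sigma`
#'   (list of K d x d matrices).
#' @export
make_init <- function(Y, K, strategy = c("kmeans", "random"), seed = 1L) {
  strategy <- match.arg(strategy)
  Y <- as.matrix(Y)
  d <- ncol(Y)
  pooled <- diag(apply(Y, 2L, stats::var), d)
  pooled <- pooled + diag(1e-12 + 1e-6 * mean(diag(pooled)), d)
  if (strategy == "kmeans") {
    km <- kmeans_fit(Y, K, n_restarts = 10L, seed = seed)
    init <- list(pi = rep(1 / K, K), mu = km$centroids,
                 Sigma = rep(list(pooled), K))
  } else {
    R <- withr::with_seed(seed, matrix(stats::runif(nrow(Y) * K), ncol = K))
    R <- R / rowSums(R)
    ms <- .gmm_mstep(Y, R, ridge = 1e-6 * mean(diag(pooled)))
    init <- ms[c("pi", "mu", "Sigma")]
  }
  structure(init, class = "init_spec")
}

# log N(y | mu, Sigma) for all rows of Y, via Cholesky
.log_dmvnorm <- function(Y, mu, Sigma) {
  d <- ncol(Y)
  ch <- chol(Sigma)
  z <- forwardsolve(t(ch), t(Y) - mu)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

.gmm_mstep <- function(Y, R, ridge) {
  n <- nrow(Y); d <- ncol(Y); K <- ncol(R)
  Nk <- colSums(R)
  pi_k <- Nk / n
  mu <- (t(R) %*% Y) / Nk
  Sigma <- vector("list", K)
  for (k in seq_len(K)) {
    Yc <- sweep(Y, 2L, mu[k, ], "-")
    S <- crossprod(Yc * R[, k], Yc) / Nk[k]
    Sigma[[k]] <- (S + t(S)) / 2 + diag(ridge, d)
  }
  list(pi = pi_k, mu = mu, Sigma = Sigma, Nk = Nk)
}

# Shared EM engine. `graph = NULL` runs classical EM; a neighbor_graph
# activates the spatial regularization: the E-step responsibility becomes
# r_ik proportional to pi_k N(y_i | mu_k, Sigma_k) s_ik where s_ik is the
# previous iteration's responsibilities averaged over voxel i's 26-connected
# masked neighbors (synchronous update; first iteration uses a uniform s).
.em_engine <- function(Y, K, init, tol, max_iter, seed, graph = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y); d <- ncol(Y)
  if (n < K) stop("need at least K observations")
  if (any(!is.finite(Y))) stop("non-finite input")
  if (is.null(init)) init <- make_init(Y, K, "kmeans", seed)
  pooled_diag <- mean(apply(Y, 2L, stats::var))
  ridge <- max(1e-6 * pooled_diag, 1e-300)
  pi_k <- init$pi; mu <- init$mu; Sigma <- init$Sigma
  constrained <- !is.null(graph)
  R_prev <- NULL
  trace <- numeric(0)
  collapses <- 0L
  monotone <- TRUE
  for (it in seq_len(max_iter)) {
    # spatial term, scaled so a uniform neighborhood contributes exactly 0:
    # a per-row constant rescaling that leaves responsibilities unchanged and
    # makes the empty-graph objective coincide with the plain log-likelihood
    logS <- if (!constrained) NULL else if (is.null(R_prev))
      matrix(0, n, K) else log(pmax(K * neighbor_average(R_prev, graph), 1e-300))
    logp <- vapply(seq_len(K),
                   function(k) log(pmax(pi_k[k], 1e-300)) + .log_dmvnorm(Y, mu[k, ], Sigma[[k]]),
                   numeric(n))
    if (constrained) logp <- logp + logS
    mx <- apply(logp, 1L, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    R <- exp(logp - lse)
    obj <- sum(lse)
    trace <- c(trace, obj)
    if (it > 1L) {
      if (obj < trace[it - 1L] - 1e-8) monotone <- FALSE
      rel <- abs(obj - trace[it - 1L]) / max(abs(trace[it - 1L]), 1e-300)
      if (rel < tol) { R_prev <- R; break }
    }
    ms <- .gmm_mstep(Y, R, ridge)
    dead <- which(ms$Nk < 1)
    if (length(dead)) {
      collapses <- collapses + length(dead)
      if (collapses > 3L)
        stop("mixture component collapsed repeatedly (> 3 re-seeds)")
      worst <- order(apply(R, 1L, max))    # least-confident voxels
      for (j in seq_along(dead)) {
        k <- dead[j]
        seedvox <- worst[j]
        ms$mu[k, ] <- Y[seedvox, ]
        ms$Sigma[[k]] <- diag(pooled_diag + ridge, d)
        ms$pi[k] <- 1 / K
        if (constrained) {
          # give the revived component spatial support around its seed voxel,
          # otherwise the mean-field prior crushes it again immediately
          supp <- c(seedvox, graph$nbrs[[seedvox]])
          R[supp, ] <- (1 - 0.9) * R[supp, , drop = FALSE] / rowSums(R[supp, , drop = FALSE])
          R[supp, k] <- R[supp, k] + 0.9
        }
      }
      ms$pi <- ms$pi / sum(ms$pi)
      message("re-seeded collapsed component(s): ", paste(dead, collapse = ","))
    }
    pi_k <- ms$pi; mu <- ms$mu; Sigma <- ms$Sigma
    R_prev <- R
  }
  if (!monotone && !constrained)
    message("EM objective decreased beyond tolerance (unexpected for standard GMM)")
  params <- structure(list(K = K, pi = pi_k, mu = mu, Sigma = Sigma),
                      class = "mixture_params")
  resp <- structure(list(R = R_prev, trace = trace, iterations = length(trace),
                         converged = length(trace) < max_iter,
                         monotone = monotone),
                    class = "responsibility_field")
  list(params = params, responsibilities = resp)
}

#' Standard Gaussian mixture model via EM
#'
#' Classical EM with full covariances and a covariance ridge of
#' 1e-6 x mean pooled variance; the log-likelihood trace is returned and is
#' non-decreasing up to numerical tolerance.
#'
#' @param Y N x d numeric matrix (features or embedding coordinates).
#' @param K number of components.
#' @param init an `init_spec` from [make_init()], or NULL for the default
#'   seeded K-means initialization.
#' @param tol relative objective-change stopping tolerance.
#' @param max_iter iteration cap.
#' @param seed integer seed (used only when `init` is NULL).
#' @return list with `params` (`mixture_params`: pi, mu, Sigma) and
#'   `responsibilities` (`responsibility_field`: R, trace, iterations).
#' @export
gmm_fit <- function(Y, K, init = NULL, tol = 1e-6, max_iter = 500L,
                    seed = 1L) {
  .em_engine(Y, K, init, tol, max_iter, seed, graph = NULL)
}

#' Spatially constrained Gaussian mixture model
#'
#' The E-step responsibility of voxel i for class k is proportional to
#' pi_k N(y_i | mu_k, Sigma_k) s_ik, where s_ik averages the previous
#' iteration's responsibilities over the voxel's 26-connected masked
#' neighbors: a voxel is more likely to be assigned a tissue class when its
#' spatial neighbors already carry that class, and vice versa. The first
#' iteration uses a uniform spatial prior; with an empty neighbor graph the
#' fit reduces to the standard GMM. The regularized objective
#' sum_i log sum_k pi_k N(y_i) s_ik is traced; it is not guaranteed
#' monotone and a non-monotone trace is recorded, not an error.
#'
#' @param Y N x d matrix (embedding coordinates in the full pipeline).
#' @param G a `neighbor_graph` over the same row order (image space).
#' @inheritParams gmm_fit
#' @return as [gmm_fit()].
#' @export
constrained_gmm_fit <- function(Y, G, K, init = NULL, tol = 1e-6,
                                max_iter = 500L, seed = 1L) {
  stopifnot(inherits(G, "neighbor_graph"))
  .em_engine(Y, K, init, tol, max_iter, seed, graph = G)
}
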