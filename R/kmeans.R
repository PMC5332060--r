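#' K-means clustering (Lloyd's algorithm, spread-out seeding)
#'
#' Baseline partitional clusterer. Each restart seeds the first centroid at
#' a random data point and the remaining centroids greedily at the point
#' farthest (maximin) from the centroids chosen so far, then iterates
#' Lloyd's assignment/update steps to convergence. The best of `n_restarts`
#' runs by within-cluster sum of squares is returned. An emptied cluster is
#' re-seeded at the point farthest from its centroid assignment. Fully
#' deterministic given `seed`.
#'
#' @param Y N x d numeric matrix.
#' @param K number of clusters (K <= N).
#' @param n_restarts independent seeded restarts (default 10).
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap per restart.
#' @return list with `centroids` (K x d), `labels` (length N, in 1..K),
#'   `inertia` (total within-cluster sum of squares), `iterations`.
#' @export
kmeans_fit <- function(Y, K, n_restarts = 10L, seed = 1L, max_iter = 100L) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < K) stop("need at least K points")
  if (any(!is.finite(Y))) stop("non-finite input")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # restart 1 seeds deterministically at the maximin points; later
    # restarts sample spread-out seeds with probability proportional to the
    # squared distance, so ties and symmetric traps differ across restarts
    style <- if (r == 1L) "maximin" else "d2"
    fit <- withr::with_seed(seed + r - 1L, .lloyd_once(Y, K, max_iter, style))
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best
}

.sqdist_to <- function(Y, C) {
  # N x K matrix of squared Euclidean distances
  outer(rowSums(Y^2), rep(1, nrow(C))) - 2 * Y %*% t(C) +
    outer(rep(1, nrow(Y)), rowSums(C^2))
}

.lloyd_once <- function(Y, K, max_iter, style = "maximin") {
  n <- nrow(Y)
  # greedy spread-out seeding
  idx <- sample.int(n, 1L)
  cent <- Y[idx, , drop = FALSE]
  while (nrow(cent) < K) {
    d2 <- .sqdist_to(Y, cent)
    mind <- pmax(apply(d2, 1L, min), 0)
    nxt <- if (style == "maximin" || sum(mind) == 0) which.max(mind) else
      sample.int(n, 1L, prob = mind)
    cent <- rbind(cent, Y[nxt, , drop = FALSE])
  }
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- .sqdist_to(Y, cent)
    new_labels <- max.col(-d2, ties.method = if (style == "maximin")
      "first" else "random")
    for (k in seq_len(K)) {                      # empty cluster -> farthest point
      if (!any(new_labels == k)) {
        far <- which.max(d2[cbind(seq_len(n), new_labels)])
        cent[k, ] <- Y[far, ]
        new_labels[far] <- k
      }
    }
    for (k in seq_len(K))
      cent[k, ] <- colMeans(Y[new_labels == k, , drop = FALSE])
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  # Hartigan-style swap refinement: move single points between clusters
  # while the exact objective change is negative; escapes Lloyd fixed
  # points that are not partition-optimal
  cnt <- tabulate(labels, K)
  for (sweep in seq_len(50L)) {
    moved <- FALSE
    for (i in seq_len(n)) {
      j <- labels[i]
      if (cnt[j] <= 1L) next
      dj <- sum((Y[i, ] - cent[j, ])^2)
      gain_out <- cnt[j] / (cnt[j] - 1L) * dj
      dl <- rowSums(sweep(cent, 2L, Y[i, ], "-")^2)
      cost_in <- cnt / (cnt + 1L) * dl
      cost_in[j] <- Inf
      l <- which.min(cost_in)
      if (cost_in[l] < gain_out - 1e-12) {
        cent[l, ] <- (cent[l, ] * cnt[l] + Y[i, ]) / (cnt[l] + 1L)
        cent[j, ] <- (cent[j, ] * cnt[j] - Y[i, ]) / (cnt[j] - 1L)
        cnt[l] <- cnt[l] + 1L; cnt[j] <- cnt[j] - 1L
        labels[i] <- l
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  d2 <- .sqdist_to(Y, cent)
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(centroids = cent, labels = labels, inertia = inertia, iterations = it)
}
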