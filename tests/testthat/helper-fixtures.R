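# Shared fixtures, built in code at test time.

# tiny fully-masked stack with deterministic values
tiny_stack <- function(shape = c(4L, 3L, 2L), nmap = 2L, seed = 42L) {
  maps <- withr::with_seed(seed, {
    out <- lapply(seq_len(nmap), function(p)
      array(stats::rnorm(prod(shape), mean = 10 * p), dim = shape))
    names(out) <- paste0("map", seq_len(nmap))
    out
  })
  mp_stack(maps, array(1L, dim = shape))
}

# standard small phantom used across suites (kept small for runtime)
small_phantom <- function(seed = 1L, shape = c(14L, 14L, 8L), ...) {
  generate_phantom(phantom_spec(shape = shape, seed = seed, ...))
}

# brute-force 26-neighbour lists by scanning all voxel pairs
brute_neighbors <- function(coords) {
  n <- nrow(coords)
  lapply(seq_len(n), function(i) {
    cheb <- apply(abs(sweep(coords, 2L, coords[i, ], "-")), 1L, max)
    which(cheb == 1L)
  })
}

# exhaustive K-partition minimum within-cluster sum of squares
brute_kmeans_inertia <- function(Y, K) {
  n <- nrow(Y)
  best <- Inf
  labels <- rep(1L, n)
  repeat {
    if (length(unique(labels)) == K) {
      w <- 0
      for (k in seq_len(K)) {
        pts <- Y[labels == k, , drop = FALSE]
        ctr <- colMeans(pts)
        w <- w + sum(sweep(pts, 2L, ctr, "-")^2)
      }
      best <- min(best, w)
    }
    # odometer increment over K^n label assignments
    i <- 1L
    while (i <= n && labels[i] == K) { labels[i] <- 1L; i <- i + 1L }
    if (i > n) break
    labels[i] <- labels[i] + 1L
  }
  best
}

# build a segmentation_result directly from a label volume + maps
fake_seg <- function(labels, maps, mask = NULL, K = max(labels)) {
  if (is.null(mask)) mask <- array(as.integer(labels > 0), dim = dim(labels))
  stack <- mp_stack(maps, mask)
  fm <- extract_features(stack)
  lab_vec <- labels[srsc:::.lin_index(fm$coords, fm$shape)]
  R <- matrix(0, length(lab_vec), K)
  R[cbind(seq_along(lab_vec), lab_vec)] <- 1
  srsc:::.build_segmentation(fm, stack, R, run_config(method = "gmm", K = K))
}
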