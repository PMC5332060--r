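#' Default per-class parameter distributions for the phantom
#'
#' Class-conditional means and SDs of the five parameter maps for the three
#' tissue classes (rows: necrotic, peri-necrotic, viable). The ADC column
#' reproduces the printed class statistics of the segmented tumors
#' (1252.68 +/- 628.48, 1132.2 +/- 466.72, 598.46 +/- 344.67, in
#' 1e-6 mm^2/s). The T2/T2* columns are synthetic: no class values are
#' published, so they are fixed once from 7T mouse-tumor physiology -
#' relaxation times lengthen with necrosis, and the iron-oxide contrast
#' agent shortens post-contrast T2/T2* most strongly in perfused viable
#' tissue, weakly in unperfused necrosis.
#'
#' @return list with `means` and `sds`, 3 x 5 matrices (classes x
#'   parameters ADC, T2_pre, T2_post, T2s_pre, T2s_post).
#' @export
default_class_params <- function() {
  params <- c("ADC", "T2_pre", "T2_post", "T2s_pre", "T2s_post")
  cls <- c("necrotic", "peri-necrotic", "viable")
  means <- matrix(c(
    1252.68, 85, 80, 42, 38,     # necrotic: high ADC, long T2, little uptake
    1132.20, 68, 55, 30, 20,     # peri-necrotic: intermediate
    598.46,  52, 30, 24,  9      # viable: low ADC, strong contrast uptake
  ), nrow = 3L, byrow = TRUE, dimnames = list(cls, params))
  sds <- matrix(c(
    628.48, 12, 12, 8, 8,
    466.72, 10, 10, 6, 5,
    344.67,  8,  8, 5, 3
  ), nrow = 3L, byrow = TRUE, dimnames = list(cls, params))
  list(means = means, sds = sds)
}

#' Phantom specification
#'
#' Describes a synthetic multiparametric tumor: grid geometry, target class
#' fractions, class-conditional feature distributions and voxel-level noise.
#'
#' @param shape grid dimensions (default 24 x 24 x 12).
#' @param spacing voxel size in mm.
#' @param geometry `"concentric_shells"` (ellipsoidal tumor with necrotic
#'   core, peri-necrotic rim, viable outer shell), `"two_blobs"` (two
#'   spatially contiguous blocks, 2 classes) or `"halfmoon_embed"`.
#' @param fractions target class fractions, summing to 1.
#' @param class_means,class_sds K x P matrices of per-class parameter
#'   means/SDs; default [default_class_params()].
#' @param noise_mult multiplier applied to every class SD (i.i.d. additive
#'   noise level; 1 = the stated class SDs).
#' @param flip_rate salt-and-pepper rate in [0, 0.5): fraction of voxels
#'   whose features are redrawn from another class's distribution (the
#'   truth label is unchanged).
#' @param dist `"normal"` or `"t"` (heavy-tailed, df = 4, scaled to the
#'   same SD).
#' @param seed integer seed; the phantom is bit-identical given the seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(24L, 24L, 12L), spacing = c(0.5, 0.5, 0.5),
                         geometry = c("concentric_shells", "two_blobs",
                                      "halfmoon_embed"),
                         fractions = c(necrotic = 0.15,
                                       `peri-necrotic` = 0.25,
                                       viable = 0.60),
                         class_means = NULL, class_sds = NULL,
                         noise_mult = 1, flip_rate = 0,
                         dist = c("normal", "t"), seed = 1L) {
  geometry <- match.arg(geometry)
  dist <- match.arg(dist)
  if (abs(sum(fractions) - 1) > 1e-9) stop("class fractions must sum to 1")
  if (any(fractions < 0)) stop("negative class fraction")
  if (flip_rate < 0 || flip_rate >= 0.5) stop("flip rate must be in [0, 0.5)")
  if (noise_mult < 0) stop("noise multiplier must be >= 0")
  dp <- default_class_params()
  if (is.null(class_means)) class_means <- dp$means
  if (is.null(class_sds)) class_sds <- dp$sds
  if (any(class_sds < 0)) stop("SDs must be >= 0")
  structure(list(shape = as.integer(shape), spacing = as.double(spacing),
                 geometry = geometry, fractions = fractions,
                 class_means = class_means, class_sds = class_sds,
                 noise_mult = noise_mult, flip_rate = flip_rate,
                 dist = dist, seed = as.integer(seed)),
            class = "phantom_spec")
}

# one draw per voxel from the class-conditional distribution
.draw_features <- function(labels, means, sds, noise_mult, dist) {
  n <- length(labels)
  P <- ncol(means)
  X <- matrix(0, n, P, dimnames = list(NULL, colnames(means)))
  for (p in seq_len(P)) {
    noise <- if (dist == "t") stats::rt(n, df = 4) / sqrt(2) else stats::rnorm(n)
    X[, p] <- means[labels, p] + sds[labels, p] * noise_mult * noise
  }
  X
}

#' Generate a synthetic multiparametric tumor phantom
#'
#' Builds the stated geometry, draws voxel features from the
#' class-conditional distributions, optionally corrupts a fraction of voxels
#' with salt-and-pepper flips (features redrawn from another class; truth
#' label unchanged), and returns the stack together with the ground-truth
#' label volume and realized fractions. Deterministic given `spec$seed`.
#'
#' For `concentric_shells` the tumor mask is an ellipsoid inscribed in the
#' grid and the core/rim radii are set from the empirical quantiles of the
#' normalized ellipsoidal radius, so realized hard fractions land within
#' +/- 2 percentage points of the targets (an error otherwise: grid too
#' small). `two_blobs` splits the mask into two contiguous blocks.
#'
#' @param spec a [phantom_spec()].
#' @return list with `stack` ([mp_stack]), `truth` (3-D label array,
#'   0 outside mask), `fractions` (`tissue_fractions` computed from the
#'   realized labels), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$geometry == "halfmoon_embed") return(halfmoon_embed(spec))
  shape <- spec$shape
  ctr <- (shape + 1) / 2
  ax <- pmax(shape / 2 - 0.5, 1)
  idx <- as.matrix(expand.grid(i = seq_len(shape[1L]), j = seq_len(shape[2L]),
                               k = seq_len(shape[3L])))
  rho <- sqrt(((idx[, 1L] - ctr[1L]) / ax[1L])^2 +
              ((idx[, 2L] - ctr[2L]) / ax[2L])^2 +
              ((idx[, 3L] - ctr[3L]) / ax[3L])^2)
  inmask <- rho <= 1
  if (sum(inmask) < 10L * length(spec$fractions)) stop("grid too small")
  lab_vec <- integer(length(rho))
  nmask <- sum(inmask)
  if (spec$geometry == "concentric_shells") {
    if (length(spec$fractions) != 3L) stop("concentric_shells needs 3 classes")
    # rank thresholding on the ellipsoidal radius: the innermost
    # round(f1*N) voxels form the core, the next round(f2*N) the rim
    # (stable order breaks the grid-symmetry ties deterministically)
    ord <- order(rho[inmask])
    n1 <- round(spec$fractions[1L] * nmask)
    n2 <- round(cumsum(spec$fractions)[2L] * nmask) - n1
    cls <- rep(3L, nmask)
    cls[ord[seq_len(n1)]] <- 1L
    cls[ord[n1 + seq_len(n2)]] <- 2L
    lab_vec[inmask] <- cls
  } else {                                   # two_blobs: split along axis 1
    if (length(spec$fractions) != 2L) stop("two_blobs needs 2 classes")
    ord <- order(idx[inmask, 1L])
    n1 <- round(spec$fractions[1L] * nmask)
    cls <- rep(2L, nmask)
    cls[ord[seq_len(n1)]] <- 1L
    lab_vec[inmask] <- cls
  }
  realized <- tabulate(lab_vec[inmask], nbins = length(spec$fractions)) / sum(inmask)
  if (any(abs(realized - spec$fractions) > 0.02))
    stop("grid too small to realize fraction targets within 2 percentage points")
  mask <- array(as.integer(lab_vec > 0L), dim = shape)
  truth <- array(lab_vec, dim = shape)
  # features in the package's raster row order, then scattered to the grid
  coords <- .mask_coords(mask)
  lin <- .lin_index(coords, shape)
  row_lab <- truth[lin]
  X <- withr::with_seed(spec$seed, {
    X <- .draw_features(row_lab, spec$class_means, spec$class_sds,
                        spec$noise_mult, spec$dist)
    if (spec$flip_rate > 0) {
      nflip <- round(spec$flip_rate * nrow(X))
      if (nflip > 0L) {
        fl <- sample.int(nrow(X), nflip)
        K <- nrow(spec$class_means)
        other <- vapply(row_lab[fl], function(l)
          sample(setdiff(seq_len(K), l), 1L), integer(1))
        X[fl, ] <- .draw_features(other, spec$class_means, spec$class_sds,
                                  spec$noise_mult, spec$dist)
      }
    }
    X
  })
  maps <- lapply(seq_len(ncol(X)), function(p)
    scatter_to_grid(X[, p], coords, shape))
  names(maps) <- colnames(X)
  stack <- mp_stack(maps, mask, spacing = spec$spacing)
  f <- structure(list(fractions = stats::setNames(realized,
                                                  names(spec$fractions)),
                      basis = "hard", n_voxels = sum(inmask)),
                 class = "tissue_fractions")
  list(stack = stack, truth = truth, fractions = f, spec = spec)
}

#' Two-crescent (half-moon) phantom
#'
#' A non-convex benchmark: voxel features of the two classes lie on two
#' interleaved crescent manifolds in the first two parameters (the
#' remaining parameters are pure low-amplitude noise), while spatially each
#' class occupies one contiguous half of the tumor mask. Partitional
#' clusterers that assume convex clusters cannot separate the crescents;
#' a spectral embedding can.
#'
#' @param spec a [phantom_spec()] with 2-entry `fractions` (default split
#'   0.5/0.5 when the spec carries 3 classes) and `noise_mult` scaling the
#'   crescent noise SD (base 0.08 on a unit-radius crescent).
#' @return as [generate_phantom()]: `stack`, `truth`, `fractions`, `spec`.
#' @export
halfmoon_embed <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  mask <- array(1L, dim = shape)
  coords <- .mask_coords(mask)
  half <- coords[, 1L] < shape[1L] / 2
  row_lab <- ifelse(half, 1L, 2L)
  n <- nrow(coords)
  pnames <- colnames(spec$class_means)
  noise_sd <- 0.08 * spec$noise_mult
  X <- withr::with_seed(spec$seed, {
    theta <- stats::runif(n, 0, pi)
    a <- cbind(cos(theta), sin(theta))                 # upper crescent
    b <- cbind(1 - cos(theta), 0.5 - sin(theta))       # interleaved lower
    M <- ifelse(cbind(row_lab, row_lab) == 1L, a, b)
    M <- M + matrix(stats::rnorm(2L * n, sd = noise_sd), n, 2L)
    cbind(M, matrix(stats::rnorm(3L * n, sd = noise_sd), n, 3L))
  })
  colnames(X) <- pnames
  maps <- lapply(seq_len(ncol(X)), function(p)
    scatter_to_grid(X[, p], coords, shape))
  names(maps) <- pnames
  truth <- scatter_to_grid(row_lab, coords, shape)
  realized <- tabulate(row_lab, nbins = 2L) / n
  f <- structure(list(fractions = stats::setNames(realized, c("moon_1", "moon_2")),
                      basis = "hard", n_voxels = n),
                 class = "tissue_fractions")
  list(stack = mp_stack(maps, mask, spacing = spec$spacing),
       truth = truth, fractions = f, spec = spec)
}

#' Seeded phantom cohort
#'
#' Generates `n` concentric-shell phantoms whose per-subject fraction
#' targets vary (necrotic ~ U(0.08, 0.30), peri-necrotic ~ U(0.15, 0.35),
#' viable the remainder), emulating a cohort of tumors with differing
#' composition so fraction correlations across subjects are informative.
#'
#' @param n number of subjects.
#' @param seed cohort seed (subject s uses `seed * 1000 + s` for its
#'   phantom draw).
#' @param shape,noise_mult,flip_rate passed to [phantom_spec()].
#' @return list of [generate_phantom()] results.
#' @export
phantom_cohort <- function(n = 5L, seed = 1L, shape = c(24L, 24L, 12L),
                           noise_mult = 1, flip_rate = 0) {
  targets <- withr::with_seed(seed, {
    nec <- stats::runif(n, 0.08, 0.30)
    per <- stats::runif(n, 0.15, 0.35)
    cbind(nec, per, 1 - nec - per)
  })
  lapply(seq_len(n), function(s) {
    fr <- c(necrotic = unname(targets[s, 1L]),
            `peri-necrotic` = unname(targets[s, 2L]),
            viable = unname(targets[s, 3L]))
    generate_phantom(phantom_spec(shape = shape, fractions = fr,
                                  noise_mult = noise_mult,
                                  flip_rate = flip_rate,
                                  seed = seed * 1000L + s))
  })
}
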