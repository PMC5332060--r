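#' Multiparametric MRI stack
#'
#' Container for a set of co-registered 3-D scalar parameter maps (by
#' convention ADC in 1e-6 mm^2/s and T2/T2* pre/post contrast in ms), a
#' binary tumor mask and the voxel geometry. All clustering in this package
#' operates on the mask-true voxels of such a stack.
#'
#' @param maps named list of 3-D numeric arrays, all with identical
#'   dimensions.
#' @param mask 3-D array of 0/1 (same dimensions as the maps).
#' @param spacing voxel size in mm, length 3.
#' @param affine optional 4x4 voxel-to-world matrix carried through to all
#'   outputs; defaults to `diag(c(spacing, 1))`.
#' @return object of class `mp_stack` with elements `maps`, `mask`,
#'   `spacing`, `affine`, `shape`.
#' @export
mp_stack <- function(maps, mask, spacing = c(1, 1, 1), affine = NULL) {
  if (is.null(names(maps)) || any(!nzchar(names(maps))))
    stop("maps must be a named list")
  shape <- dim(maps[[1L]])
  if (length(shape) != 3L) stop("maps must be 3-D arrays")
  for (nm in names(maps)) {
    if (!identical(dim(maps[[nm]]), shape))
      stop("grid mismatch: map '", nm, "' has shape (",
           paste(dim(maps[[nm]]), collapse = ","), ") but expected (",
           paste(shape, collapse = ","), ")")
  }
  if (!identical(dim(mask), shape))
    stop("grid mismatch: mask has shape (", paste(dim(mask), collapse = ","),
         ") but expected (", paste(shape, collapse = ","), ")")
  bad <- !(mask %in% c(0, 1))
  if (any(bad))
    stop("mask is not binary: contains values other than {0,1}")
  mask <- array(as.integer(mask), dim = shape)
  if (sum(mask) == 0L) stop("empty mask")
  inmask <- mask == 1L
  for (nm in names(maps)) {
    v <- maps[[nm]][inmask]
    if (any(!is.finite(v)))
      stop("map '", nm, "' has non-finite values inside the mask")
  }
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(maps = maps, mask = mask, spacing = as.double(spacing),
                 affine = affine, shape = as.integer(shape)),
            class = "mp_stack")
}

#' @export
print.mp_stack <- function(x, ...) {
  cat("mp_stack: ", paste(x$shape, collapse = " x "), " grid, ",
      sum(x$mask), " masked voxels\n", sep = "")
  cat("  parameters: ", paste(names(x$maps), collapse = ", "), "\n", sep = "")
  cat("  spacing (mm): ", paste(format(x$spacing), collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Read a multiparametric stack from NIfTI files
#'
#' Loads one NIfTI volume per parameter plus a binary mask and validates them
#' into an [mp_stack]. Grids must agree exactly; affines must agree within
#' `1e-4` elementwise (the first map's affine is recorded). The mask is
#' thresholded at 0.5, but values that are not 0/1 up to rounding fuzz are an
#' error rather than silently binarized.
#'
#' @param paths named character vector mapping parameter name to volume file.
#' @param mask_path path of the binary mask volume.
#' @return an [mp_stack].
#' @export
read_stack <- function(paths, mask_path) {
  if (is.null(names(paths))) stop("paths must be named by parameter")
  vols <- lapply(paths, read_nifti)
  mk <- read_nifti(mask_path)
  ref <- vols[[1L]]
  for (nm in names(vols)) {
    if (max(abs(vols[[nm]]$affine - ref$affine)) > 1e-4)
      stop("affine mismatch: map '", nm, "' disagrees with '",
           names(vols)[1L], "' beyond 1e-4")
  }
  mv <- mk$data
  thr <- ifelse(mv > 0.5, 1, 0)
  if (any(abs(mv - thr) > 1e-3))
    stop("mask is not binary: values other than {0,1} present")
  mp_stack(lapply(vols, `[[`, "data"), array(thr, dim = dim(mv)),
           spacing = ref$pixdim, affine = ref$affine)
}

# Deterministic raster order of mask-true voxels: 0-based (i,j,k) sorted
# lexicographically with the LAST axis fastest. R's which() is column-major
# (first axis fastest), so reorder explicitly.
.mask_coords <- function(mask) {
  co <- which(mask == 1L, arr.ind = TRUE) - 1L
  co <- co[order(co[, 1L], co[, 2L], co[, 3L]), , drop = FALSE]
  dimnames(co) <- NULL
  co
}

# 1-based linear index into an array of dim `shape` for 0-based coords
.lin_index <- function(coords, shape) {
  coords[, 1L] + shape[1L] * (coords[, 2L] + shape[2L] * coords[, 3L]) + 1L
}

#' Extract the masked voxel-wise feature matrix
#'
#' Builds the N x P matrix whose row i is the feature vector of the i-th
#' mask-true voxel: the co-registered parameter values concatenated in the
#' order the maps are stored. Row order is a fixed deterministic raster scan
#' of the mask (0-based coordinates, last axis fastest), so identical input
#' always yields bit-identical rows and coordinates.
#'
#' @param stack an [mp_stack].
#' @return object of class `feature_matrix`: `X` (N x P), `coords` (N x 3,
#'   0-based), `param_names`, `standardized` flag, plus grid geometry used to
#'   scatter results back to the volume.
#' @export
extract_features <- function(stack) {
  stopifnot(inherits(stack, "mp_stack"))
  coords <- .mask_coords(stack$mask)
  idx <- .lin_index(coords, stack$shape)
  X <- vapply(stack$maps, function(m) m[idx], numeric(nrow(coords)))
  X <- matrix(X, nrow = nrow(coords),
              dimnames = list(NULL, names(stack$maps)))
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    vx <- unique(bad[, 1L])
    stop("non-finite feature values at voxel coords: ",
         paste(apply(coords[utils::head(vx, 5L), , drop = FALSE], 1L,
                     paste, collapse = ","), collapse = "; "))
  }
  structure(list(X = X, coords = coords, param_names = names(stack$maps),
                 standardized = FALSE, center = NULL, scale = NULL,
                 zero_var = NULL, shape = stack$shape, spacing = stack$spacing,
                 affine = stack$affine, mask = stack$mask),
            class = "feature_matrix")
}

#' Z-score the feature matrix per parameter
#'
#' Standardizes each column over the masked voxels to mean 0 and unit sample
#' standard deviation (denominator N-1). Columns with zero variance map to
#' all-zero and are flagged in `zero_var`. The location/scale used are stored
#' for inverse mapping; applying [standardize()] to an already standardized
#' matrix is a numerical no-op.
#'
#' @param fm a `feature_matrix`.
#' @return the standardized `feature_matrix`.
#' @export
standardize <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  ctr <- colMeans(fm$X)
  scl <- apply(fm$X, 2L, stats::sd)
  zero <- !is.finite(scl) | scl < .Machine$double.eps * 1e3
  scl[zero] <- 1
  Z <- sweep(sweep(fm$X, 2L, ctr, "-"), 2L, scl, "/")
  Z[, zero] <- 0
  out <- fm
  out$X <- Z
  if (isTRUE(fm$standardized)) {
    # compose with the previously stored transform so center/scale always
    # refer to the original raw data
    out$center <- fm$center + fm$scale * ctr
    out$scale <- fm$scale * scl
    out$zero_var <- fm$zero_var | zero
  } else {
    out$center <- ctr
    out$scale <- scl
    out$zero_var <- zero
  }
  out$standardized <- TRUE
  out
}

# Scatter a per-voxel vector back onto the 3-D grid (fill outside mask)
scatter_to_grid <- function(values, coords, shape, fill = 0) {
  vol <- array(fill, dim = shape)
  vol[.lin_index(coords, shape)] <- values
  vol
}
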