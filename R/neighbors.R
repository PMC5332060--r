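#' Build the 26-connectivity neighbor graph of the masked voxels
#'
#' For each masked voxel, lists the masked voxels among its 26-connected
#' grid neighbors (all voxels at Chebyshev distance 1 in 3-D). The graph is
#' symmetric, has no self-links, and is restricted to the mask.
#'
#' @param coords N x 3 matrix of 0-based voxel coordinates (row order of the
#'   feature matrix).
#' @param shape grid dimensions, length 3.
#' @return object of class `neighbor_graph`: `nbrs` (list of integer vectors
#'   of row indices), `edges` (two-column matrix of directed edges, used for
#'   fast averaging), `n`.
#' @export
build_neighbor_graph <- function(coords, shape) {
  n <- nrow(coords)
  if (n == 0L) stop("no voxels")
  if (any(coords < 0L) || any(coords >= matrix(shape, n, 3L, byrow = TRUE)))
    stop("coords outside grid")
  lin <- .lin_index(coords, shape)
  if (anyDuplicated(lin)) stop("coords must be unique")
  lookup <- integer(prod(shape))
  lookup[lin] <- seq_len(n)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(offs != 0L) > 0L, , drop = FALSE]   # 26 offsets
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[r, ], "+")
    ok <- nb[, 1L] >= 0L & nb[, 1L] < shape[1L] &
          nb[, 2L] >= 0L & nb[, 2L] < shape[2L] &
          nb[, 3L] >= 0L & nb[, 3L] < shape[3L]
    j <- integer(n)
    j[ok] <- lookup[.lin_index(nb[ok, , drop = FALSE], shape)]
    hit <- which(j > 0L)
    from <- c(from, hit)
    to <- c(to, j[hit])
  }
  nbrs <- split(to, factor(from, levels = seq_len(n)))
  names(nbrs) <- NULL
  structure(list(nbrs = nbrs, edges = cbind(from = from, to = to), n = n),
            class = "neighbor_graph")
}

#' Empty neighbor graph (disables spatial regularization)
#'
#' @param n number of voxels.
#' @return a `neighbor_graph` with no edges; under it the spatially
#'   constrained GMM reduces to the standard GMM.
#' @export
empty_neighbor_graph <- function(n) {
  structure(list(nbrs = rep(list(integer(0)), n),
                 edges = cbind(from = integer(0), to = integer(0)), n = n),
            class = "neighbor_graph")
}

#' Average class probabilities over each voxel's 26-neighborhood
#'
#' s_ik = mean over the masked neighbors j of voxel i of r_jk. Voxels with
#' no masked neighbor get the uninformative uniform row 1/K. Rows of the
#' result sum to 1 whenever the rows of `R` do.
#'
#' @param R N x K responsibility matrix (rows on the simplex).
#' @param G a `neighbor_graph` matching the row order of `R`.
#' @return N x K matrix of neighborhood-averaged probabilities.
#' @export
neighbor_average <- function(R, G) {
  stopifnot(inherits(G, "neighbor_graph"), nrow(R) == G$n)
  K <- ncol(R)
  S <- matrix(1 / K, nrow(R), K)
  if (nrow(G$edges) == 0L) return(S)
  deg <- tabulate(G$edges[, 1L], nbins = G$n)
  acc <- rowsum(R[G$edges[, 2L], , drop = FALSE],
                group = G$edges[, 1L], reorder = TRUE)
  has <- sort(unique(G$edges[, 1L]))
  S[has, ] <- acc / deg[has]
  S
}
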