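#' Pipeline run configuration
#'
#' Validated bag of settings for [run_segmentation()]. Unknown keys are
#' rejected; numeric settings are range-checked.
#'
#' @param method `"srsc"` (RBF affinity, normalized-Laplacian embedding,
#'   spatially constrained GMM), or a baseline: `"kmeans"`, `"fcm"`,
#'   `"gmm"`. Baselines run on the standardized raw features, not the
#'   embedding (they are compared as stand-alone methods).
#' @param K number of tissue classes (default 3).
#' @param sigma_rule `"median"` or `"fixed"`.
#' @param sigma_value RBF scale when `sigma_rule = "fixed"`.
#' @param laplacian `"sym"` or `"rw"`.
#' @param n_eigen number of Laplacian eigenvectors (default K + 1: with a
#'   median-heuristic sigma the affinity graph is strongly connected and the
#'   class structure spreads beyond the first K eigenvectors; one surplus
#'   eigenvector restores the boundary information, while many more
#'   destabilize the row-normalized embedding).
#' @param row_normalize unit-row normalization of the embedding rows
#'   (default FALSE: projecting onto the unit sphere distorts relative class
#'   masses when tissue fractions are imbalanced, which destabilizes the
#'   mixture fit; the option remains for the classical recipe).
#' @param standardize z-score features per parameter before clustering.
#' @param spatial use the 26-neighbor graph for SRSC (FALSE substitutes an
#'   empty graph, reducing the constrained GMM to a standard GMM on the
#'   embedding; used for ablation and reduction checks).
#' @param fcm_m FCM fuzziness exponent (> 1).
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter EM / FCM iteration cap.
#' @param seed integer seed for every stochastic step.
#' @param restarts K-means restarts.
#' @param baselines_on_embedding run baseline methods on the spectral
#'   embedding instead of the standardized features (ablation flag).
#' @return object of class `run_config`.
#' @export
run_config <- function(method = c("srsc", "kmeans", "fcm", "gmm"), K = 3L,
                       sigma_rule = c("median", "fixed"), sigma_value = NULL,
                       laplacian = c("sym", "rw"), n_eigen = NULL,
                       row_normalize = FALSE, standardize = TRUE,
                       spatial = TRUE, fcm_m = 2, tol = 1e-6,
                       max_iter = 500L, seed = 1L, restarts = 10L,
                       baselines_on_embedding = FALSE) {
  method <- match.arg(method)
  sigma_rule <- match.arg(sigma_rule)
  laplacian <- match.arg(laplacian)
  if (K < 1L) stop("K must be >= 1")
  if (fcm_m <= 1) stop("fcm_m must exceed 1")
  if (tol <= 0 || max_iter < 1L || restarts < 1L) stop("invalid tolerance/iteration settings")
  if (sigma_rule == "fixed" && (is.null(sigma_value) || sigma_value <= 0))
    stop("fixed sigma rule requires a positive sigma_value")
  structure(list(method = method, K = as.integer(K), sigma_rule = sigma_rule,
                 sigma_value = sigma_value, laplacian = laplacian,
                 n_eigen = if (is.null(n_eigen)) as.integer(K) + 1L else as.integer(n_eigen),
                 row_normalize = isTRUE(row_normalize),
                 standardize = isTRUE(standardize), spatial = isTRUE(spatial),
                 fcm_m = fcm_m, tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 baselines_on_embedding = isTRUE(baselines_on_embedding)),
            class = "run_config")
}

#' Load a run configuration from a JSON or YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are rejected.
#'
#' @param path config file (`.json`, or `.yaml`/`.yml` when the `yaml`
#'   package is available).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, cfg)
}

.build_segmentation <- function(fm, stack, R, cfg, sigma = NA_real_,
                                trace = numeric(0), iterations = NA_integer_) {
  K <- ncol(R)
  labels_vec <- max.col(R, ties.method = "first")
  labels <- scatter_to_grid(labels_vec, fm$coords, fm$shape, fill = 0)
  probs <- lapply(seq_len(K), function(k)
    scatter_to_grid(R[, k], fm$coords, fm$shape, fill = 0))
  inmask_idx <- .lin_index(fm$coords, fm$shape)
  ci <- data.frame(class = seq_len(K),
                   voxels = tabulate(labels_vec, nbins = K))
  for (pn in names(stack$maps)) {
    v <- stack$maps[[pn]][inmask_idx]
    ci[[paste0("mean_", pn)]] <- vapply(seq_len(K), function(k) {
      x <- v[labels_vec == k]; if (length(x)) mean(x) else NA_real_
    }, numeric(1))
    ci[[paste0("sd_", pn)]] <- vapply(seq_len(K), function(k) {
      x <- v[labels_vec == k]; if (length(x) > 1L) stats::sd(x) else NA_real_
    }, numeric(1))
  }
  seg <- structure(list(labels = labels, probabilities = probs,
                        class_info = ci, mask = stack$mask,
                        spacing = stack$spacing, affine = stack$affine,
                        method = cfg$method, sigma = sigma,
                        seed = cfg$seed, trace = trace,
                        iterations = iterations, config = unclass(cfg)),
                   class = "segmentation_result")
  if (K >= 3L && "ADC" %in% names(stack$maps)) seg <- assign_tissue_names(seg)
  seg$fractions <- compute_fractions(seg, "hard")
  seg
}

#' Run one segmentation method on a multiparametric stack
#'
#' The SRSC path composes: feature extraction over the mask, per-parameter
#' z-scoring, RBF affinity at the chosen sigma, normalized-Laplacian
#' spectral embedding, and the spatially constrained GMM driven by the
#' 26-neighbor image-space graph; classes are then named from their mean
#' ADC. Baseline methods (K-means, FCM, standard GMM) run on the
#' standardized raw features. The returned result carries a manifest
#' (config, sigma used, seed, iteration trace) sufficient to reproduce the
#' run bit-identically.
#'
#' @param cfg a [run_config()].
#' @param stack an [mp_stack] (or NULL to read from `paths`/`mask_path`).
#' @param paths,mask_path NIfTI inputs, used when `stack` is NULL.
#' @param out_dir if non-NULL, outputs are written via
#'   [write_segmentation()].
#' @return a `segmentation_result`.
#' @export
run_segmentation <- function(cfg, stack = NULL, paths = NULL,
                             mask_path = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(stack)) {
    if (is.null(paths) || is.null(mask_path))
      stop("stage io: provide either a stack or input paths")
    stack <- read_stack(paths, mask_path)
  }
  if (sum(stack$mask) < cfg$K) stop("stage io: mask has fewer voxels than K")
  fm <- extract_features(stack)
  if (cfg$standardize) fm <- standardize(fm)
  sigma <- NA_real_
  trace <- numeric(0); iterations <- NA_integer_
  if (cfg$method == "srsc" || cfg$baselines_on_embedding) {
    sigma <- choose_sigma(fm, cfg$sigma_rule, cfg$sigma_value, seed = cfg$seed)
    A <- compute_affinity(fm, sigma)
    emb <- spectral_embed(A, cfg$n_eigen, row_normalize = cfg$row_normalize,
                          laplacian = cfg$laplacian)
    Y <- emb$Y
  }
  if (cfg$method == "srsc") {
    G <- if (cfg$spatial) build_neighbor_graph(fm$coords, fm$shape)
         else empty_neighbor_graph(nrow(fm$coords))
    fit <- constrained_gmm_fit(Y, G, cfg$K, tol = cfg$tol,
                               max_iter = cfg$max_iter, seed = cfg$seed)
    R <- fit$responsibilities$R
    trace <- fit$responsibilities$trace
    iterations <- fit$responsibilities$iterations
  } else {
    Yb <- if (cfg$baselines_on_embedding) Y else fm$X
    if (cfg$method == "kmeans") {
      km <- kmeans_fit(Yb, cfg$K, n_restarts = cfg$restarts, seed = cfg$seed)
      R <- matrix(0, nrow(Yb), cfg$K)
      R[cbind(seq_len(nrow(Yb)), km$labels)] <- 1
      iterations <- km$iterations
    } else if (cfg$method == "fcm") {
      fc <- fcm_fit(Yb, cfg$K, m = cfg$fcm_m, tol = cfg$tol,
                    max_iter = cfg$max_iter, seed = cfg$seed)
      R <- fc$U; trace <- fc$objective; iterations <- fc$iterations
    } else {
      fit <- gmm_fit(Yb, cfg$K, tol = cfg$tol, max_iter = cfg$max_iter,
                     seed = cfg$seed)
      R <- fit$responsibilities$R
      trace <- fit$responsibilities$trace
      iterations <- fit$responsibilities$iterations
    }
  }
  seg <- .build_segmentation(fm, stack, R, cfg, sigma = as.double(sigma),
                             trace = trace, iterations = iterations)
  if (!is.null(out_dir)) write_segmentation(seg, out_dir)
  seg
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("segmentation_result (", x$method, "): ",
      paste(dim(x$labels), collapse = " x "), " grid, ",
      sum(x$mask), " masked voxels, K = ", nrow(x$class_info), "\n", sep = "")
  print(x$class_info)
  cat("hard fractions:\n")
  print(round(x$fractions$fractions, 4))
  invisible(x)
}

#' Write a segmentation to disk
#'
#' Writes one integer label volume (0 outside the mask, 1..K inside), K
#' per-class probability volumes in [0,1], all NIfTI with the input affine,
#' plus a JSON sidecar holding class names, per-class parameter means,
#' fractions, sigma, seed and the convergence trace.
#'
#' @param seg a `segmentation_result`.
#' @param out_dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_segmentation <- function(seg, out_dir) {
  stopifnot(inherits(seg, "segmentation_result"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  p <- file.path(out_dir, "labels.nii.gz")
  write_nifti(seg$labels, p, affine = seg$affine, pixdim = seg$spacing,
              datatype = "int16")
  written <- c(written, p)
  tissue <- seg$class_info$tissue %||% paste0("class_", seg$class_info$class)
  for (k in seq_along(seg$probabilities)) {
    p <- file.path(out_dir, sprintf("prob_%02d_%s.nii.gz", k,
                                    gsub("[^a-zA-Z0-9_]", "_", tissue[k])))
    write_nifti(seg$probabilities[[k]], p, affine = seg$affine,
                pixdim = seg$spacing)
    written <- c(written, p)
  }
  sidecar <- list(method = seg$method, tissue = tissue,
                  class_info = seg$class_info,
                  fractions = as.list(seg$fractions$fractions),
                  sigma = seg$sigma, seed = seg$seed,
                  iterations = seg$iterations, trace = seg$trace,
                  config = seg$config,
                  version = as.character(utils::packageVersion("srsc")))
  p <- file.path(out_dir, "segmentation.json")
  jsonlite::write_json(sidecar, p, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  written <- c(written, p)
  invisible(written)
}

#' Compare methods on a common cohort
#'
#' Runs each method on every subject and assembles per-method fraction
#' tables plus the method-comparison correlation table (rows: Viable,
#' Necrotic, Peri-necrotic, All; one column of Pearson r per method)
#' against the reference fractions. When ground-truth label volumes are
#' supplied, matched accuracy and ARI per subject are included.
#'
#' @param stacks list of [mp_stack] objects (one per subject).
#' @param ref list of named reference fraction vectors (one per subject;
#'   names must include the tissue names used by the segmentations).
#' @param methods character vector of methods to compare.
#' @param base_cfg a [run_config()] whose non-method settings are shared.
#' @param truths optional list of ground-truth label volumes.
#' @return list with `correlations` (tissue x method data.frame of r),
#'   `details` (per-method [correlate_fractions()] output), `fractions`
#'   (long data.frame), `agreement` (per method/subject accuracy + ARI, if
#'   truths given), `segmentations`.
#' @export
run_comparison <- function(stacks, ref, methods = c("srsc", "kmeans", "fcm",
                                                    "gmm"),
                           base_cfg = run_config(), truths = NULL) {
  stopifnot(length(stacks) == length(ref))
  details <- list(); segs <- list(); frac_rows <- list(); agree_rows <- list()
  for (m in methods) {
    cfg <- base_cfg
    cfg$method <- m
    preds <- lapply(seq_along(stacks), function(s) {
      cfg$seed <- base_cfg$seed + s - 1L
      run_segmentation(cfg, stack = stacks[[s]])
    })
    segs[[m]] <- preds
    fr <- lapply(preds, compute_fractions, basis = "hard")
    details[[m]] <- correlate_fractions(fr, ref)
    for (s in seq_along(fr)) {
      frac_rows[[length(frac_rows) + 1L]] <- data.frame(
        method = m, subject = s, tissue = names(fr[[s]]$fractions),
        predicted = unname(fr[[s]]$fractions),
        reference = unname(ref[[s]][names(fr[[s]]$fractions)]))
      if (!is.null(truths)) {
        mm <- match_labels(preds[[s]]$labels, truths[[s]])
        agree_rows[[length(agree_rows) + 1L]] <- data.frame(
          method = m, subject = s, accuracy = mm$accuracy, ari = mm$ari)
      }
    }
  }
  order_rows <- c("viable", "necrotic", "peri-necrotic", "All")
  corr <- data.frame(tissue = c("Viable", "Necrotic", "Peri-necrotic", "All"))
  for (m in methods)
    corr[[m]] <- details[[m]]$r[match(order_rows, details[[m]]$tissue)]
  list(correlations = corr, details = details,
       fractions = do.call(rbind, frac_rows),
       agreement = if (length(agree_rows)) do.call(rbind, agree_rows) else NULL,
       segmentations = segs)
}
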