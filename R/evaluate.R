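#' Name tissue classes from their mean ADC
#'
#' Orders the three classes by mean raw apparent diffusion coefficient and
#' names them necrotic (highest), peri-necrotic (middle), viable (lowest);
#' free water in dead tissue diffuses readily while dense viable tumor
#' restricts diffusion. Extra classes beyond three are named `other_1`,
#' `other_2`, ... in descending ADC order. Ties on mean ADC (< 1e-9 apart)
#' are broken by the larger mean post-contrast T2 becoming necrotic (poorly
#' perfused tissue retains long T2 after an intravascular contrast agent);
#' ties are logged.
#'
#' @param seg a `segmentation_result` (class_info holds per-class raw
#'   parameter means).
#' @param adc_map name of the ADC parameter (default `"ADC"`).
#' @param t2post_map parameter used for tie-breaks (default `"T2_post"`).
#' @return `seg` with `class_info$tissue` filled.
#' @export
assign_tissue_names <- function(seg, adc_map = "ADC", t2post_map = "T2_post") {
  stopifnot(inherits(seg, "segmentation_result"))
  ci <- seg$class_info
  K <- nrow(ci)
  if (K < 3L) stop("need >=3 classes for tissue naming")
  adc_col <- paste0("mean_", adc_map)
  if (!adc_col %in% names(ci)) stop("ADC parameter '", adc_map, "' not found")
  key <- ci[[adc_col]]
  t2p_col <- paste0("mean_", t2post_map)
  if (t2p_col %in% names(ci)) {
    dup <- outer(key, key, function(a, b) abs(a - b) < 1e-9) & !diag(K)
    if (any(dup)) {
      message("mean-ADC tie broken by mean ", t2post_map)
      key <- key + 1e-9 * rank(ci[[t2p_col]]) / K
    }
  }
  ord <- order(key, decreasing = TRUE)
  tissue <- character(K)
  tissue[ord[1:3]] <- c("necrotic", "peri-necrotic", "viable")
  if (K > 3L) tissue[ord[4:K]] <- paste0("other_", seq_len(K - 3L))
  seg$class_info$tissue <- tissue
  seg
}

#' Fractional tissue populations
#'
#' The fraction of the tumor volume occupied by each class: `hard` counts
#' labeled voxels, `soft` averages the class probability over the mask.
#' Fractions sum to 1.
#'
#' @param seg a `segmentation_result`.
#' @param basis `"hard"` (default; the analog of areas of hard delineations)
#'   or `"soft"`.
#' @return object of class `tissue_fractions`: named numeric vector
#'   `fractions`, `basis`, `n_voxels`.
#' @export
compute_fractions <- function(seg, basis = c("hard", "soft")) {
  basis <- match.arg(basis)
  stopifnot(inherits(seg, "segmentation_result"))
  inmask <- seg$mask == 1L
  n <- sum(inmask)
  K <- nrow(seg$class_info)
  f <- if (basis == "hard") {
    tabulate(seg$labels[inmask], nbins = K) / n
  } else {
    vapply(seg$probabilities, function(p) mean(p[inmask]), numeric(1))
  }
  names(f) <- seg$class_info$tissue %||% paste0("class_", seq_len(K))
  structure(list(fractions = f, basis = basis, n_voxels = n),
            class = "tissue_fractions")
}

# all permutations of 1..k (k! rows)
.perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perms(k - 1L)
  out <- matrix(0L, 0L, k)
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b integer label vectors of equal length.
#' @return scalar ARI (1 = identical partitions up to relabeling, ~0 for
#'   independent labelings).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (abs(mx - expected) < .Machine$double.eps) return(0)
  (nij - expected) / (mx - expected)
}

#' Match predicted cluster indices to reference labels
#'
#' Cluster indices are arbitrary; this finds the one-to-one class matching
#' that maximizes total overlap (exact exhaustive search over permutations
#' for K <= 8; greedy above) and reports agreement metrics. When class
#' counts differ, the min(K) classes are matched and leftovers reported.
#'
#' @param pred,truth integer label volumes/vectors over the same mask
#'   support (0 = outside; compared where `truth > 0`).
#' @return list with `perm` (perm[j] = predicted class matched to truth
#'   class j), `accuracy`, `dice` (per matched truth class), `ari`,
#'   `confusion` (truth x pred), `unmatched`.
#' @export
match_labels <- function(pred, truth) {
  p <- as.integer(pred[truth > 0])
  t <- as.integer(truth[truth > 0])
  if (length(p) != length(t)) stop("pred and truth differ in mask support")
  Kt <- max(t); Kp <- max(p)
  K <- max(Kt, Kp)
  C <- matrix(0L, K, K)   # rows truth, cols pred (square-padded)
  for (i in seq_along(t)) C[t[i], p[i]] <- C[t[i], p[i]] + 1L
  if (K <= 8L) {
    pm <- .perms(K)
    scores <- apply(pm, 1L, function(s) sum(C[cbind(seq_len(K), s)]))
    perm <- pm[which.max(scores), ]
  } else {
    warning("K > 8: using greedy matching, not guaranteed optimal")
    perm <- integer(K)
    Cw <- C
    for (r in seq_len(K)) {
      ij <- which(Cw == max(Cw), arr.ind = TRUE)[1L, ]
      perm[ij[1L]] <- ij[2L]
      Cw[ij[1L], ] <- -1L; Cw[, ij[2L]] <- -1L
    }
  }
  matched <- sum(C[cbind(seq_len(K), perm)])
  dice <- vapply(seq_len(Kt), function(j) {
    inter <- C[j, perm[j]]
    2 * inter / (sum(C[j, ]) + sum(C[, perm[j]]))
  }, numeric(1))
  list(perm = perm[seq_len(Kt)],
       accuracy = matched / length(t),
       dice = dice,
       ari = adjusted_rand_index(p, t),
       confusion = C[seq_len(Kt), seq_len(Kp), drop = FALSE],
       unmatched = if (Kp > Kt) setdiff(seq_len(Kp), perm[seq_len(Kt)]) else integer(0))
}

#' Correlate predicted tissue fractions with reference fractions
#'
#' Pearson correlation per tissue class across subjects, plus a pooled
#' `All` row concatenating every (subject, tissue) pair; two-sided p-values
#' come from the t-transform of r. A tissue needs at least 3 paired
#' subjects for r to be reported; zero variance in either vector makes r
#' undefined (reported as NA with a note, not propagated).
#'
#' @param pred list of `tissue_fractions` (or named numeric vectors), one
#'   per subject.
#' @param ref list of named numeric reference fractions, one per subject,
#'   with the same tissue names.
#' @return data.frame with columns tissue, n, r, p, note.
#' @export
correlate_fractions <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("pred and ref lengths differ")
  getf <- function(x) if (inherits(x, "tissue_fractions")) x$fractions else x
  pred <- lapply(pred, getf)
  ref <- lapply(ref, getf)
  tissues <- names(pred[[1L]])
  rows <- lapply(c(tissues, "All"), function(tt) {
    if (tt == "All") {
      x <- unlist(lapply(pred, `[`, tissues), use.names = FALSE)
      y <- unlist(lapply(ref, `[`, tissues), use.names = FALSE)
    } else {
      x <- vapply(pred, `[[`, numeric(1), tt)
      y <- vapply(ref, `[[`, numeric(1), tt)
    }
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L)
      return(data.frame(tissue = tt, n = length(x), r = NA_real_,
                        p = NA_real_, note = "fewer than 3 paired subjects"))
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(tissue = tt, n = length(x), r = NA_real_,
                        p = NA_real_, note = "undefined: zero variance"))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(tissue = tt, n = length(x), r = unname(ct$estimate),
               p = ct$p.value, note = "")
  })
  do.call(rbind, rows)
}

#' Class-wise parameter statistics and nonparametric tests
#'
#' For every MRI parameter and tissue class: mean, SD, median and the
#' 5th/95th percentiles (whisker convention of the class-wise box plots),
#' a one-sample Kolmogorov-Smirnov test against a fitted normal, an omnibus
#' Kruskal-Wallis test across classes, and - when the omnibus test is
#' significant at 0.05 - pairwise Wilcoxon rank-sum tests flagged
#' significant at the Bonferroni threshold 0.05/3 = 0.0167 for the three
#' class pairs. Classes with fewer than 2 voxels are skipped and flagged.
#'
#' @param seg a `segmentation_result`.
#' @param stack the originating [mp_stack] (raw parameter values are used).
#' @param alpha pairwise Bonferroni-corrected significance threshold
#'   (default 0.05/3, printed as 0.0167).
#' @return list with `summary` (per class x parameter descriptives +
#'   KS normality p), `kruskal` (per parameter), `pairwise` (per parameter
#'   and class pair, with `significant` flag), `skipped` (classes with < 2
#'   voxels).
#' @export
classwise_parameter_stats <- function(seg, stack, alpha = 0.05 / 3) {
  stopifnot(inherits(seg, "segmentation_result"), inherits(stack, "mp_stack"))
  inmask <- seg$mask == 1L
  lab <- seg$labels[inmask]
  K <- nrow(seg$class_info)
  tissue <- seg$class_info$tissue %||% paste0("class_", seq_len(K))
  skipped <- tissue[tabulate(lab, nbins = K) < 2L]
  summary_rows <- list(); kw_rows <- list(); pw_rows <- list()
  for (pn in names(stack$maps)) {
    v <- stack$maps[[pn]][inmask]
    groups <- list()
    for (k in seq_len(K)) {
      x <- v[lab == k]
      if (length(x) < 2L) next
      groups[[tissue[k]]] <- x
      ks <- suppressWarnings(
        stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
      qs <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        parameter = pn, tissue = tissue[k], n = length(x),
        mean = mean(x), sd = stats::sd(x), p5 = qs[1L], median = qs[2L],
        p95 = qs[3L], ks_p = ks$p.value)
    }
    if (length(groups) >= 2L) {
      kw <- stats::kruskal.test(groups)
      kw_rows[[length(kw_rows) + 1L]] <-
        data.frame(parameter = pn, statistic = unname(kw$statistic),
                   p = kw$p.value, significant = kw$p.value < 0.05)
      if (kw$p.value < 0.05) {
        cmb <- utils::combn(names(groups), 2L)
        for (cc in seq_len(ncol(cmb))) {
          a <- cmb[1L, cc]; b <- cmb[2L, cc]
          wt <- suppressWarnings(
            stats::wilcox.test(groups[[a]], groups[[b]]))
          pw_rows[[length(pw_rows) + 1L]] <- data.frame(
            parameter = pn, tissue_a = a, tissue_b = b, p = wt$p.value,
            significant = wt$p.value < alpha)
        }
      }
    }
  }
  list(summary = do.call(rbind, summary_rows),
       kruskal = do.call(rbind, kw_rows),
       pairwise = if (length(pw_rows)) do.call(rbind, pw_rows) else NULL,
       skipped = skipped, alpha = alpha)
}
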