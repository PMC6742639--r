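#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` over the features of an
#' abundance matrix, computed with `vegan::vegdist()`.
#'
#' @param abundance A feature-by-sample tibble (id column first), e.g.
#'   from [biomass_matrix()].
#' @return A `dist` object over the samples, entries in \[0, 1\].
#' @export
bray_curtis <- function(abundance) {
  m <- tbl_to_matrix(as_tibble(abundance))
  if (any(m < 0)) abort("abundances must be non-negative")
  zero <- colSums(m) == 0
  if (any(zero))
    abort(paste0("sample(s) with zero total abundance: ",
                 paste(colnames(m)[zero], collapse = ", ")),
          class = "mipror_domain_error")
  vegan::vegdist(t(m), method = "bray")
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of `-D^2 / 2` and
#' eigendecomposition. Axes are ordered by descending eigenvalue; negative
#' eigenvalues are dropped (no Lingoes/Cailliez correction) and variance
#' proportions are computed over the positive eigenvalues only, so the
#' coordinates reproduce the distances exactly when the matrix is
#' Euclidean-embeddable.
#'
#' @param distances A `dist` object or symmetric matrix.
#' @return An object of class `mipro_ordination`: `points` (tibble with
#'   `Sample` and `Axis1..AxisK`), `proportions`, `eig` and `type`.
#' @export
pcoa_ord <- function(distances) {
  d <- stats::as.dist(distances)
  n <- attr(d, "Size")
  if (n < 3) abort("PCoA needs at least 3 samples")
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  tol <- max(abs(fit$eig)) * 1e-8
  pos <- fit$eig > tol
  k <- min(sum(pos), ncol(fit$points))
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(k))
  structure(list(points = matrix_to_tbl(pts, "Sample"),
                 proportions = fit$eig[pos] / sum(fit$eig[pos]),
                 eig = fit$eig, type = "pcoa"),
            class = "mipro_ordination")
}

#' @export
print.mipro_ordination <- function(x, ...) {
  pct <- round(100 * x$proportions[seq_len(min(2, length(x$proportions)))], 1)
  cat(sprintf("<mipro_ordination:%s> %d samples; axis 1-2: %s%% of variance\n",
              x$type, nrow(x$points), paste(pct, collapse = "% / ")))
  invisible(x)
}

# All distinct assignments of `sizes` group labels to n items, as a matrix
# with one labeling per column. Used for exact ANOSIM p-values.
enumerate_labelings <- function(sizes) {
  n <- sum(sizes)
  recurse <- function(remaining_idx, sizes_left) {
    if (length(sizes_left) == 1)
      return(matrix(rep(length(sizes), length(remaining_idx)), ncol = 1,
                    dimnames = NULL))
    g <- length(sizes) - length(sizes_left) + 1
    picks <- combn(length(remaining_idx), sizes_left[1])
    out <- list()
    for (c_i in seq_len(ncol(picks))) {
      sel <- picks[, c_i]
      sub <- recurse(remaining_idx[-sel], sizes_left[-1])
      block <- matrix(NA_integer_, nrow = length(remaining_idx),
                      ncol = ncol(sub))
      block[sel, ] <- g
      block[-sel, ] <- sub
      out[[c_i]] <- block
    }
    do.call(cbind, out)
  }
  recurse(seq_len(n), sizes)
}

anosim_r_stat <- function(rank_d, labels, n) {
  same <- outer(labels, labels, "==")[lower.tri(matrix(0, n, n))]
  (mean(rank_d[!same]) - mean(rank_d[same])) / (n * (n - 1) / 4)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of group separation on a distance matrix. All pairwise
#' distances are ranked (average ranks on ties) and
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`.
#' The p-value is obtained by permuting group labels: exactly, by
#' enumerating every distinct labeling, when their number does not exceed
#' `exact_limit` (then `p` is the fraction of labelings with permuted
#' `R >= observed R`, the observed labeling included); otherwise by
#' `n_permutations` uniform random permutations with the add-one estimator
#' `p = (1 + #{R_perm >= R_obs}) / (1 + n_permutations)`.
#'
#' @param distances A `dist` object or symmetric matrix.
#' @param labels Group label per sample (in distance-matrix order).
#' @param n_permutations Random permutations when not exact (default 999).
#' @param seed Optional seed for the random permutations.
#' @param exact_limit Enumerate exhaustively when the number of distinct
#'   labelings is at most this (default 1024).
#' @return An object of class `anosim_result` with elements `R`, `p`,
#'   `method` (`"exact"` or `"permutation"`), `n_permutations`, `groups`.
#' @export
anosim_test <- function(distances, labels, n_permutations = 999,
                        seed = NULL, exact_limit = 1024) {
  d <- stats::as.dist(distances)
  n <- attr(d, "Size")
  labels <- as.character(labels)
  if (length(labels) != n)
    abort("`labels` must have one entry per sample")
  sizes <- table(labels)
  if (length(sizes) < 2) abort("ANOSIM needs at least 2 groups")
  if (any(sizes < 2))
    abort(paste0("every group needs at least 2 samples; offending: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")),
          class = "mipror_domain_error")

  rank_d <- rank(as.vector(d))
  lab_int <- as.integer(factor(labels))
  R_obs <- anosim_r_stat(rank_d, lab_int, n)

  n_labelings <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (n_labelings <= exact_limit + 0.5) {
    labelings <- enumerate_labelings(as.integer(sort(sizes, decreasing = TRUE)))
    # sizes sorted descending; R is invariant to which label a group gets,
    # only the partition into groups of given sizes matters
    Rs <- apply(labelings, 2, function(l) anosim_r_stat(rank_d, l, n))
    p <- mean(Rs >= R_obs - 1e-12)
    method <- "exact"
    n_perm <- ncol(labelings)
  } else {
    do_perm <- function() {
      Rs <- vapply(seq_len(n_permutations), function(i)
        anosim_r_stat(rank_d, sample(lab_int), n), numeric(1))
      (1 + sum(Rs >= R_obs - 1e-12)) / (1 + n_permutations)
    }
    p <- if (is.null(seed)) do_perm() else with_seed(seed, do_perm())
    method <- "permutation"
    n_perm <- n_permutations
  }
  structure(list(R = R_obs, p = p, method = method,
                 n_permutations = n_perm, groups = sizes, seed = seed),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f, p = %.4g (%s, %d labelings/permutations)\n",
              x$R, x$p, x$method, x$n_permutations))
  invisible(x)
}

#' Shannon-Wiener diversity per sample
#'
#' `H = -sum(p_i log p_i)` over each sample's taxon proportions (natural
#' log), computed with `vegan::diversity()`.
#'
#' @param abundance A feature-by-sample tibble (id column first).
#' @return A tibble (`Sample`, `shannon`).
#' @export
shannon_index <- function(abundance) {
  m <- tbl_to_matrix(as_tibble(abundance))
  zero <- colSums(m) == 0
  if (any(zero))
    abort(paste0("sample(s) with zero total abundance: ",
                 paste(colnames(m)[zero], collapse = ", ")),
          class = "mipror_domain_error")
  h <- vegan::diversity(t(m), index = "shannon")
  tibble(Sample = colnames(m), shannon = as.numeric(h))
}

#' Principal component analysis of a functional abundance matrix
#'
#' Samples are observations and functional categories variables; columns
#' are mean-centered but not scaled to unit variance (all categories share
#' one intensity unit). Components are ordered by descending explained
#' variance.
#'
#' @param fmat A [cog_rollup()]-style tibble (category column first, one
#'   column per sample).
#' @param scale. Scale variables to unit variance (default `FALSE`).
#' @return An object of class `mipro_ordination` with `points` (scores),
#'   `proportions`, `loadings` and `type = "pca"`.
#' @export
pca_functions <- function(fmat, scale. = FALSE) {
  m <- tbl_to_matrix(as_tibble(fmat))
  if (ncol(m) < 3 || nrow(m) < 2)
    abort("PCA needs at least 3 samples and 2 categories")
  X <- t(m)
  if (all(apply(X, 2, var) < 1e-30))
    abort("constant matrix: no variance to decompose",
          class = "mipror_domain_error")
  fit <- prcomp(X, center = TRUE, scale. = scale.)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  pts <- fit$x
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  structure(list(points = matrix_to_tbl(pts, "Sample"),
                 proportions = expl, loadings = fit$rotation,
                 type = "pca"),
            class = "mipro_ordination")
}
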