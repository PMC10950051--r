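#' Pairwise-complete absolute-Spearman similarity matrix
#'
#' For every marker pair the similarity is |Spearman rho| computed over the
#' subjects where both markers are observed; a subject is only removed from
#' a given pair's calculation if it is missing one of the two markers in
#' question. The number of complete pairs is recorded per entry, and entries
#' with fewer than `min_pairs` complete pairs (or a constant side) are
#' flagged undefined (`NA`). Undefined entries abort clustering rather than
#' being silently imputed.
#'
#' @param data Panel tibble (already sparse-subject-excluded).
#' @param markers Marker columns to correlate.
#' @param min_pairs Minimum complete pairs for a defined entry.
#' @return An object of class `marker_similarity`: a list with `sim`
#'   (p x p, diagonal 1), `n_pairs` (p x p integer) and `markers`.
#' @export
build_similarity <- function(data, markers = panel_markers(data),
                             min_pairs = 3L) {
  x <- as.matrix(data[, markers, drop = FALSE])
  p <- ncol(x)
  if (p < 2) abort_stage("similarity", "need at least 2 markers")
  if (nrow(x) < 2) abort_stage("similarity", "need at least 2 subjects")
  sim <- diag(1, p)
  npair <- matrix(0L, p, p, dimnames = list(markers, markers))
  diag(npair) <- as.integer(colSums(!is.na(x)))
  dimnames(sim) <- list(markers, markers)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      r <- spearman_abs(x[, i], x[, j], min_pairs = min_pairs)
      sim[i, j] <- sim[j, i] <- r$abs_rho
      npair[i, j] <- npair[j, i] <- r$n_pairs
    }
  }
  structure(list(sim = sim, n_pairs = npair, markers = markers,
                 min_pairs = as.integer(min_pairs)),
            class = "marker_similarity")
}

#' @export
print.marker_similarity <- function(x, ...) {
  cat(sprintf("<marker_similarity> %d markers, %d undefined entr%s\n",
              length(x$markers), sum(is.na(x$sim)) / 2,
              if (sum(is.na(x$sim)) == 2) "y" else "ies"))
  invisible(x)
}

#' WPGMA agglomerative linkage on a similarity matrix
#'
#' Converts similarity to the dissimilarity `d = 1 - sim` and merges the
#' closest pair of clusters iteratively. The WPGMA update gives the two
#' merged members' distances equal weight regardless of cluster size:
#' `d(ab, c) = (d(a, c) + d(b, c)) / 2`. Ties in merge selection are broken
#' by the lexicographically smallest pair of cluster indices, so dendrograms
#' are deterministic for fixed input. Heights are checked for monotonicity
#' and a warning is logged if inversions occur (possible on non-metric
#' pairwise-complete input).
#'
#' @param sim A `marker_similarity` object, or a symmetric similarity matrix
#'   in `[0, 1]` with unit diagonal.
#' @return An object of class `wpgma_dendrogram`: a list with `merge`
#'   (hclust-style, negative entries are leaves), `height`, `order`,
#'   `labels`.
#' @export
wpgma_linkage <- function(sim) {
  s <- if (inherits(sim, "marker_similarity")) sim$sim else as.matrix(sim)
  if (any(is.na(s)))
    abort_stage("linkage",
                "similarity matrix has undefined entries (too few complete pairs)")
  labels <- colnames(s) %||% paste0("V", seq_len(ncol(s)))
  d <- 1 - s
  p <- ncol(d)
  if (p < 2) abort_stage("linkage", "need at least 2 leaves")
  # active cluster ids: negative = leaf index, positive = merge step
  id <- -seq_len(p)
  active <- rep(TRUE, p)
  merge <- matrix(0L, p - 1, 2)
  height <- numeric(p - 1)
  for (step in seq_len(p - 1)) {
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(p - 1)) {
      if (!active[i]) next
      for (j in (i + 1):p) {
        if (!active[j]) next
        if (d[i, j] < best - 1e-15) { # strict: first (smallest) pair wins ties
          best <- d[i, j]; bi <- i; bj <- j
        }
      }
    }
    if (!is.finite(best)) abort_stage("linkage", "non-finite distance")
    merge[step, ] <- sort(c(id[bi], id[bj]))
    height[step] <- best
    # WPGMA update into slot bi
    for (k in seq_len(p)) {
      if (!active[k] || k == bi || k == bj) next
      d[bi, k] <- d[k, bi] <- (d[bi, k] + d[bj, k]) / 2
    }
    active[bj] <- FALSE
    id[bi] <- step
  }
  if (any(diff(height) < -1e-10))
    warning("non-monotone merge heights: input dissimilarity is non-metric",
            call. = FALSE)
  structure(list(merge = merge, height = height,
                 order = dendrogram_order(merge), labels = labels,
                 method = "wpgma"),
            class = "wpgma_dendrogram")
}

# leaf order without branch crossings, from an hclust-style merge matrix
dendrogram_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' @export
print.wpgma_dendrogram <- function(x, ...) {
  cat(sprintf("<wpgma_dendrogram> %d leaves, merge heights %.3f..%.3f\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' @export
as.hclust.wpgma_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "mcquitty",
                 call = match.call(), dist.method = "1 - |spearman rho|"),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the `k - 1` highest (latest) merges. Labels are arbitrary but
#' stable for fixed input.
#'
#' @param dendro A `wpgma_dendrogram`.
#' @param k Number of clusters, `1 <= k <= p`.
#' @return A tibble with `marker` and `cluster` (integer).
#' @export
cut_clusters <- function(dendro, k) {
  p <- length(dendro$labels)
  if (k < 1 || k > p) abort_stage("cut", "k out of range")
  cl <- stats::cutree(as.hclust(dendro), k = k)
  tibble::tibble(marker = dendro$labels, cluster = as.integer(cl))
}

#' Select the cluster count by a permutation-averaged PCA elbow
#'
#' For each of `n_permutations` replicates a uniformly random
#' `holdout_fraction` of subjects is dropped and the scree of the
#' pairwise-complete correlation matrix is computed on the retained
#' subjects. The scree curves are averaged and the elbow is the index
#' maximizing the second forward difference of the mean curve
#' (`lambda[i] - 2 lambda[i+1] + lambda[i+2]`); ties go to the smaller k.
#'
#' @param data Panel tibble (preprocessed).
#' @param n_permutations Number of holdout replicates.
#' @param holdout_fraction Fraction of subjects dropped per replicate.
#' @param seed Optional seed for the permutation draws.
#' @param markers Marker columns.
#' @return An object of class `elbow_selection`: list with `k`,
#'   `mean_scree`, `n_permutations`, `holdout_fraction`.
#' @export
select_k_elbow <- function(data, n_permutations = 1000L,
                           holdout_fraction = 0.2, seed = NULL,
                           markers = panel_markers(data)) {
  if (n_permutations < 1) abort_stage("elbow", "n_permutations must be >= 1")
  x <- as.matrix(data[, markers, drop = FALSE])
  n <- nrow(x)
  n_drop <- floor(holdout_fraction * n)
  if (n - n_drop < 3) abort_stage("elbow", "holdout leaves fewer than 3 subjects")
  if (!is.null(seed)) set.seed(seed)
  acc <- numeric(ncol(x))
  for (b in seq_len(n_permutations)) {
    keep <- if (n_drop > 0) -sample.int(n, n_drop) else seq_len(n)
    acc <- acc + pca_scree(x[keep, , drop = FALSE], quiet = TRUE)
  }
  mean_scree <- acc / n_permutations
  structure(list(k = elbow_point(mean_scree), mean_scree = mean_scree,
                 n_permutations = as.integer(n_permutations),
                 holdout_fraction = holdout_fraction),
            class = "elbow_selection")
}

#' @rdname select_k_elbow
#' @param scree A descending eigenvalue vector.
#' @export
elbow_point <- function(scree) {
  p <- length(scree)
  if (p < 3) return(1L)
  d2 <- scree[1:(p - 2)] - 2 * scree[2:(p - 1)] + scree[3:p]
  as.integer(which.max(d2))
}

#' @export
print.elbow_selection <- function(x, ...) {
  cat(sprintf("<elbow_selection> k = %d (%d permutations, %g%% holdout)\n",
              x$k, x$n_permutations, 100 * x$holdout_fraction))
  invisible(x)
}

#' Edge list of marker pairs above a similarity threshold
#'
#' @param sim A `marker_similarity` object.
#' @param threshold Similarity threshold in `[0, 1]`; strictly greater-than.
#' @return A tibble with `marker_a`, `marker_b`, `similarity`, `n_pairs`,
#'   sorted by similarity descending.
#' @export
edge_list <- function(sim, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  m <- sim$sim
  idx <- which(upper.tri(m), arr.ind = TRUE)
  out <- tibble::tibble(
    marker_a = sim$markers[idx[, 1]],
    marker_b = sim$markers[idx[, 2]],
    similarity = m[idx],
    n_pairs = sim$n_pairs[idx])
  out <- out[!is.na(out$similarity) & out$similarity > threshold, ]
  dplyr::arrange(out, dplyr::desc(.data$similarity))
}

#' Export a dendrogram as a Newick string
#'
#' Merge heights become node heights; branch lengths are height differences.
#'
#' @param dendro A `wpgma_dendrogram`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to file.
#' @export
as_newick <- function(dendro, path = NULL) {
  phy <- ape::as.phylo(as.hclust(dendro))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
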