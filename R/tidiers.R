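# broom-style tidiers

#' @export
tidy.marker_similarity <- function(x, ...) {
  idx <- which(upper.tri(x$sim), arr.ind = TRUE)
  tibble::tibble(marker_a = x$markers[idx[, 1]],
                 marker_b = x$markers[idx[, 2]],
                 similarity = x$sim[idx],
                 n_pairs = x$n_pairs[idx])
}

#' @export
tidy.wpgma_dendrogram <- function(x, ...) {
  tibble::tibble(step = seq_along(x$height),
                 cluster_a = x$merge[, 1],
                 cluster_b = x$merge[, 2],
                 height = x$height)
}

#' @export
tidy.elbow_selection <- function(x, ...) {
  p <- length(x$mean_scree)
  d2 <- c(x$mean_scree[1:(p - 2)] - 2 * x$mean_scree[2:(p - 1)] +
            x$mean_scree[3:p], NA, NA)
  tibble::tibble(component = seq_len(p), eigenvalue = x$mean_scree,
                 second_difference = d2)
}

#' @export
glance.elbow_selection <- function(x, ...) {
  tibble::tibble(k = x$k, n_permutations = x$n_permutations,
                 holdout_fraction = x$holdout_fraction)
}

#' @export
tidy.feature_weights <- function(x, ...) x$weights

#' @export
glance.feature_weights <- function(x, ...) {
  tibble::tibble(folds_passed = x$folds_passed, folds = nrow(x$folds),
                 gate_sens = unname(x$gate["sens"]),
                 gate_spec = unname(x$gate["spec"]),
                 n_weak = sum(x$weights$weak))
}

#' @export
tidy.curvature_forest <- function(x, ...) feature_importance(x)

#' @export
glance.curvature_forest <- function(x, ...) {
  tibble::tibble(method = x$method, n_trees = x$n_cycles,
                 min_leaf = x$min_leaf, max_splits = x$max_splits,
                 learn_rate = if (x$method == "boost") x$learn_rate else NA_real_)
}

#' @export
tidy.clustering_report <- function(x, ...) x$clusters

#' @export
glance.clustering_report <- function(x, ...) {
  tibble::tibble(cohort = x$cohort, n = x$n, k = x$k,
                 n_edges = nrow(x$edges), seed = x$seed)
}

#' @export
tidy.feature_selection_report <- function(x, ...) x$weights$weights

#' @export
glance.feature_selection_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(task = x$task, n = x$n, seed = x$seed),
                   glance(x$weights))
}
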