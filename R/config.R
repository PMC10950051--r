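#' Analysis configuration
#'
#' Bundles every tunable of the pipeline. The `full` profile mirrors the
#' reference protocol (1000 elbow permutations, 300 Bayesian-optimization
#' iterations, 10 outer and 10 inner CV folds); the `scaled` profile is a
#' cheaper setting for routine testing (100 permutations, 30 BO iterations,
#' 3 inner folds, narrower learning-cycle and split-budget search ranges)
#' that changes precision only, never the code path.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param profile `"full"` or `"scaled"`; sets the defaults below.
#' @param n_permutations Elbow permutation count.
#' @param holdout_fraction Subject fraction dropped per elbow permutation.
#' @param cv_folds Outer cross-validation folds for feature selection.
#' @param bo_iterations Bayesian-optimization budget per outer fold.
#' @param inner_cv_folds Inner CV folds estimating the BO objective.
#' @param gate_sens,gate_spec Held-out sensitivity/specificity a fold's best
#'   model must reach to contribute feature weights.
#' @param weak_threshold Rescaled weight below which a feature is flagged
#'   weak.
#' @param edge_threshold Similarity threshold for edge-list export.
#' @param sparse_subject_fraction Missing-fraction above which a subject is
#'   excluded.
#' @param min_pairs Minimum complete pairs for a similarity entry to be
#'   defined.
#' @param n_surrogates Maximum surrogate splits stored per node.
#' @param prune Prune bagged trees on their out-of-bag rows.
#' @param n_cycles_range,learn_rate_range,max_splits_range Hyperparameter
#'   search ranges (log scale). `max_splits_range = NULL` means up to
#'   `n - 1`.
#' @param min_leaf_max Upper bound for the minimum-leaf-size search;
#'   `NULL` means `max(2, n/4)`.
#' @return A list of class `ad_config`.
#' @export
analysis_config <- function(seed = 1L,
                            profile = c("full", "scaled"),
                            n_permutations = NULL,
                            holdout_fraction = 0.2,
                            cv_folds = 10L,
                            bo_iterations = NULL,
                            inner_cv_folds = NULL,
                            gate_sens = 0.8,
                            gate_spec = 0.8,
                            weak_threshold = 0.5,
                            edge_threshold = 0.5,
                            sparse_subject_fraction = 0.5,
                            min_pairs = 3L,
                            n_surrogates = 5L,
                            prune = TRUE,
                            n_cycles_range = NULL,
                            learn_rate_range = c(1e-3, 1),
                            max_splits_range = NULL,
                            min_leaf_max = NULL) {
  profile <- match.arg(profile)
  scaled <- profile == "scaled"
  cfg <- list(
    seed = as.integer(seed),
    profile = profile,
    n_permutations = as.integer(n_permutations %||% if (scaled) 100L else 1000L),
    holdout_fraction = holdout_fraction,
    cv_folds = as.integer(cv_folds),
    bo_iterations = as.integer(bo_iterations %||% if (scaled) 30L else 300L),
    inner_cv_folds = as.integer(inner_cv_folds %||% if (scaled) 3L else 10L),
    gate_sens = gate_sens, gate_spec = gate_spec,
    weak_threshold = weak_threshold, edge_threshold = edge_threshold,
    sparse_subject_fraction = sparse_subject_fraction,
    min_pairs = as.integer(min_pairs),
    n_surrogates = as.integer(n_surrogates),
    prune = isTRUE(prune),
    n_cycles_range = n_cycles_range %||% if (scaled) c(10, 60) else c(10, 500),
    learn_rate_range = learn_rate_range,
    max_splits_range = max_splits_range %||% if (scaled) c(1, 32) else NULL,
    min_leaf_max = min_leaf_max)
  fr <- c(cfg$holdout_fraction, cfg$gate_sens, cfg$gate_spec,
          cfg$weak_threshold, cfg$sparse_subject_fraction)
  if (any(fr <= 0) || any(fr >= 1))
    abort_stage("config", "fractions must lie in (0, 1)")
  if (cfg$edge_threshold < 0 || cfg$edge_threshold > 1)
    abort_stage("config", "edge_threshold must lie in [0, 1]")
  ints <- c(cfg$n_permutations, cfg$cv_folds, cfg$bo_iterations,
            cfg$inner_cv_folds, cfg$min_pairs, cfg$n_surrogates)
  if (any(ints <= 0))
    abort_stage("config", "integer settings must be positive")
  structure(cfg, class = "ad_config")
}
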