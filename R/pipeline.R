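#' Run a clustering experiment on a cohort
#'
#' One experiment = subset to the cohort, exclude sparse subjects,
#' preprocess (z-scoring is recomputed within the analysis cohort), build the
#' pairwise-complete |Spearman| similarity matrix, select the cluster count
#' with the permutation-averaged PCA elbow, run WPGMA linkage, cut, and
#' extract the thresholded edge list. Stage errors are propagated with the
#' stage name. All randomness derives from `config$seed`.
#'
#' @param data Panel tibble (raw values; labels included).
#' @param cohort One of `"entire"`, `"preclinical"`, `"impaired"`,
#'   `"amyloid_positive"`.
#' @param config An [analysis_config()].
#' @param out_dir Optional directory to write artifacts into (Newick
#'   dendrogram, similarity and merge TSVs, edge list, config echo JSON).
#' @return An object of class `clustering_report`: list with `cohort`, `n`,
#'   `k`, `similarity`, `dendrogram`, `clusters`, `edges`, `elbow`,
#'   `config`.
#' @export
run_clustering_experiment <- function(data, cohort = "entire",
                                      config = analysis_config(),
                                      out_dir = NULL) {
  seeds <- derive_seeds(config$seed, 1)
  panel <- subset_cohort(data, cohort)
  panel <- exclude_sparse_subjects(panel, config$sparse_subject_fraction)
  panel <- preprocess(panel)
  sim <- build_similarity(panel, min_pairs = config$min_pairs)
  elbow <- select_k_elbow(panel, n_permutations = config$n_permutations,
                          holdout_fraction = config$holdout_fraction,
                          seed = seeds[1])
  dendro <- wpgma_linkage(sim)
  clusters <- cut_clusters(dendro, elbow$k)
  edges <- edge_list(sim, config$edge_threshold)
  report <- structure(
    list(cohort = cohort, n = nrow(panel), k = elbow$k, similarity = sim,
         dendrogram = dendro, clusters = clusters, edges = edges,
         elbow = elbow, config = config, seed = config$seed),
    class = "clustering_report")
  if (!is.null(out_dir)) write_clustering_report(report, out_dir)
  report
}

#' @export
print.clustering_report <- function(x, ...) {
  cat(sprintf("<clustering_report> cohort '%s': n = %d, k = %d, %d edges > %g\n",
              x$cohort, x$n, x$k, nrow(x$edges), x$config$edge_threshold))
  invisible(x)
}

write_clustering_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(out_dir, paste0("clustering_", report$cohort))
  as_newick(report$dendrogram, paste0(stem, ".nwk"))
  readr::write_tsv(tidy(report$dendrogram), paste0(stem, "_merges.tsv"),
                   progress = FALSE)
  sim_df <- tibble::as_tibble(report$similarity$sim, rownames = "marker")
  readr::write_tsv(sim_df, paste0(stem, "_similarity.tsv"), progress = FALSE)
  readr::write_tsv(report$edges, paste0(stem, "_edges.tsv"), progress = FALSE)
  readr::write_tsv(report$clusters, paste0(stem, "_clusters.tsv"),
                   progress = FALSE)
  echo <- unclass(report$config)
  echo$k_selected <- report$k
  echo$n_subjects <- report$n
  echo$cohort <- report$cohort
  jsonlite::write_json(echo, paste0(stem, "_config.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(out_dir)
}

# predictor sets per feature-selection task: outcome-defining markers are
# removed to prevent circularity (amyloid PET for the amyloid model; CDR-SB
# and MMSE for the cognition models, CDR-SB because it defines the outcome's
# scale)
task_definition <- function(task, markers = ad_marker_names()) {
  switch(task,
    amyloid_entire = list(outcome = "amyloid_positive", cohort = "entire",
                          drop = "amyloid_pet", positive = "TRUE"),
    cognition_entire = list(outcome = "cdr_group", cohort = "entire",
                            drop = c("cdr_sb", "mmse"), positive = "CDRgt0"),
    cognition_Apos = list(outcome = "cdr_group", cohort = "amyloid_positive",
                          drop = c("cdr_sb", "mmse"), positive = "CDRgt0"),
    abort_stage("feature_selection", paste0("unknown task: ", task)))
}

#' Run a feature-selection experiment
#'
#' Tasks: `amyloid_entire` predicts amyloid-PET positivity over the entire
#' cohort with the amyloid-PET marker removed from the predictors;
#' `cognition_entire` predicts cognitive impairment (CDR > 0) over the
#' entire cohort; `cognition_Apos` predicts cognitive impairment among
#' amyloid-positive subjects. Cognition tasks drop CDR-SB and MMSE from the
#' predictors. The cohort is sparse-subject-excluded and preprocessed, then
#' [feature_selection_cv()] runs the gated protocol.
#'
#' @param data Panel tibble (raw values; labels included).
#' @param task Task name (above).
#' @param config An [analysis_config()].
#' @param out_dir Optional directory for the weights TSV and config echo.
#' @return An object of class `feature_selection_report`: list with `task`,
#'   `n`, `weights` (a `feature_weights` object), `predictors`, `config`.
#' @export
run_feature_selection_experiment <- function(data, task,
                                             config = analysis_config(),
                                             out_dir = NULL) {
  td <- task_definition(task)
  panel <- subset_cohort(data, td$cohort)
  panel <- exclude_sparse_subjects(panel, config$sparse_subject_fraction)
  panel <- preprocess(panel)
  predictors <- setdiff(panel_markers(panel), td$drop)
  if (td$outcome == "cdr_group" &&
      length(unique(panel$cdr_group)) < 2)
    abort_stage("feature_selection", "outcome single-class after subsetting")
  df <- panel
  df[[td$outcome]] <- factor(as.character(df[[td$outcome]]))
  fw <- feature_selection_cv(df, td$outcome, predictors, config = config,
                             positive = td$positive)
  report <- structure(
    list(task = task, n = nrow(panel), weights = fw, predictors = predictors,
         dropped = td$drop, config = config, seed = config$seed),
    class = "feature_selection_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(out_dir, paste0("features_", task))
    write_weights_tsv(fw, paste0(stem, "_weights.tsv"))
    echo <- unclass(config)
    echo$task <- task
    echo$n_subjects <- nrow(panel)
    echo$folds_passed <- fw$folds_passed
    jsonlite::write_json(echo, paste0(stem, "_config.json"),
                         auto_unbox = TRUE, null = "null")
  }
  report
}

#' @export
print.feature_selection_report <- function(x, ...) {
  cat(sprintf("<feature_selection_report> task '%s': n = %d, %d/%d folds passed\n",
              x$task, x$n, x$weights$folds_passed, nrow(x$weights$folds)))
  print(utils::head(x$weights$weights, 5))
  invisible(x)
}
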