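#' Gated cross-validated embedded feature selection
#'
#' The reference protocol: the data are split into `config$cv_folds`
#' stratified outer folds. Within each outer fold the forest hyperparameters
#' are tuned by Bayesian optimization (each optimization step scored by a
#' separate inner cross-validation on the training portion), the incumbent
#' model is refitted on the training portion and evaluated on the held-out
#' fold. Folds whose best model reaches the sensitivity and specificity
#' gates contribute their split-gain importance vector; passing vectors are
#' averaged and then min-max rescaled to `[0, 1]`. Any feature below
#' `config$weak_threshold` after rescaling is flagged a weak predictor.
#'
#' @param data Data frame with the outcome and marker columns. The caller
#'   must already have removed outcome-defining markers (circularity guard).
#' @param outcome Binary outcome column name.
#' @param markers Candidate predictor columns.
#' @param config An [analysis_config()].
#' @param positive The positive class for sensitivity; default the second
#'   factor level.
#' @return An object of class `feature_weights`: list with `weights` (tibble
#'   `marker`, `raw`, `rescaled`, `weak`, sorted by rescaled weight
#'   descending), `folds` (per-fold hyperparameters and held-out
#'   sensitivity/specificity), `folds_passed`, `gate`.
#'   If no fold passes the gate, an error of class
#'   `admarkers_no_qualifying_model` is raised.
#' @export
feature_selection_cv <- function(data, outcome, markers,
                                 config = analysis_config(),
                                 positive = NULL) {
  d <- forest_design(data, outcome, markers)
  if (nlevels(d$y) != 2)
    abort_stage("feature_selection", "outcome must be binary")
  positive <- positive %||% levels(d$y)[2]
  seeds <- derive_seeds(config$seed, 1 + 2 * config$cv_folds)
  fold <- make_folds(d$y, config$cv_folds, seed = seeds[1])
  fold_rows <- list()
  imp <- list()
  for (f in seq_len(config$cv_folds)) {
    tr <- data[fold != f, , drop = FALSE]
    te <- data[fold == f, , drop = FALSE]
    tuned <- tune_forest(tr, outcome, markers, config = config,
                         seed = seeds[2 * f])
    h <- tuned$hyper
    fit <- grow_forest(tr, outcome, markers, method = h$method,
                       n_cycles = h$n_cycles, learn_rate = h$learn_rate,
                       min_leaf = h$min_leaf, max_splits = h$max_splits,
                       n_surrogates = config$n_surrogates,
                       prune = config$prune, seed = seeds[2 * f + 1])
    pred <- predict(fit, te, type = "class")
    ss <- sens_spec(pred, te[[outcome]], positive)
    passed <- ss$sensitivity >= config$gate_sens &&
      ss$specificity >= config$gate_spec
    if (passed) imp[[length(imp) + 1]] <- feature_importance(fit)$importance
    fold_rows[[f]] <- tibble::tibble(
      fold = f, method = h$method, n_cycles = h$n_cycles,
      learn_rate = h$learn_rate, min_leaf = h$min_leaf,
      max_splits = h$max_splits, cv_error = tuned$cv_error,
      sensitivity = ss$sensitivity, specificity = ss$specificity,
      passed = passed)
  }
  folds <- dplyr::bind_rows(fold_rows)
  if (length(imp) == 0)
    rlang::abort(sprintf(
      "no qualifying model: no CV fold reached sensitivity >= %g and specificity >= %g",
      config$gate_sens, config$gate_spec),
      class = "admarkers_no_qualifying_model")
  raw <- Reduce(`+`, imp) / length(imp)
  rescaled <- if (length(unique(raw)) >= 2) minmax_rescale(raw) else raw
  weights <- tibble::tibble(marker = markers, raw = raw, rescaled = rescaled,
                            weak = rescaled < config$weak_threshold)
  weights <- dplyr::arrange(weights, dplyr::desc(.data$rescaled))
  structure(list(weights = weights, folds = folds,
                 folds_passed = sum(folds$passed),
                 gate = c(sens = config$gate_sens, spec = config$gate_spec),
                 outcome = outcome, positive = positive,
                 config = config),
            class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf("<feature_weights> outcome '%s', %d/%d folds passed the gate\n",
              x$outcome, x$folds_passed, nrow(x$folds)))
  print(utils::head(x$weights, 5))
  invisible(x)
}

#' Write feature weights to TSV, strongest first
#'
#' @param x A `feature_weights` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_weights_tsv <- function(x, path) {
  readr::write_tsv(x$weights, path, progress = FALSE)
  invisible(path)
}
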